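#' Default planted micro-state partitions
#'
#' Each micro-state is defined by a partition of the networks into synchrony
#' groups; networks in the same group share a common phase process. The
#' curated defaults for ten networks mirror the qualitative state taxonomy
#' seen in resting-state work: a globally synchronized state, a fully
#' dys-synchronized state, and two mixed states grouping visual,
#' default-mode/frontoparietal and sensorimotor/auditory systems.
#'
#' @param n_states number of micro-states.
#' @param n_icns number of networks.
#' @return list of length `n_states`; each element a list of integer vectors
#'   partitioning `1:n_icns`.
#' @export
default_state_partitions <- function(n_states = 4L, n_icns = 10L) {
  if (n_icns == 10L && n_states <= 6L) {
    curated <- list(
      list(1:10),                                        # global synchrony
      as.list(1:10),                                     # dys-synchronized
      list(1:5, 6:10),                                   # sensory vs association
      list(c(1L, 2L, 3L, 8L, 9L, 10L), c(4L, 5L, 6L, 7L)),
      list(c(1L, 2L, 3L), c(4L, 8L, 9L, 10L), c(5L, 6L, 7L)),
      list(c(1L, 6L), c(2L, 7L), c(3L, 8L), c(4L, 9L), c(5L, 10L))
    )
    return(curated[seq_len(n_states)])
  }
  # generic fallback: state s splits the networks round-robin into s groups
  lapply(seq_len(n_states), function(s) {
    g <- min(s, n_icns)
    split(seq_len(n_icns), rep_len(seq_len(g), n_icns))
  })
}

#' Default per-state amplitude profiles
#'
#' Mean envelope amplitude (arbitrary units) per state and network. For ten
#' networks the base profile makes the medial visual, default-mode and right
#' frontoparietal networks the most active and the cerebellum the quietest,
#' scaled per state so states also differ in overall amplitude.
#'
#' @inheritParams default_state_partitions
#' @return `n_states` x `n_icns` positive matrix.
#' @export
default_amplitude_profiles <- function(n_states = 4L, n_icns = 10L) {
  base <- if (n_icns == 10L)
    c(2.5, 2, 2, 2.5, 1, 2, 2, 2, 2.5, 2)
  else rep(2, n_icns)
  out <- outer(seq(0.9, 1.2, length.out = n_states), base)
  colnames(out) <- default_icn_names(n_icns)
  out
}

#' Default condition effects
#'
#' Multiplicative per-network amplitude factors and phase-coupling
#' (concentration) modifiers for each condition. The default plants a 1.5x
#' amplitude increase of the sensorimotor and auditory networks under
#' eyes-closed, the direction reported for those systems, and no coupling
#' differences.
#'
#' @param n_icns number of networks.
#' @param ec_amp_icns indices of networks receiving the EC amplitude factor.
#' @param ec_amp_factor the planted EC/EO amplitude ratio.
#' @return named list with one element per condition, each holding
#'   `amplitude` and `coupling` factor vectors of length `n_icns`.
#' @export
default_condition_effects <- function(n_icns = 10L,
                                      ec_amp_icns = if (n_icns == 10L) c(6L, 7L) else 1L,
                                      ec_amp_factor = 1.5) {
  ec_amp <- rep(1, n_icns)
  ec_amp[ec_amp_icns] <- ec_amp_factor
  list(EO = list(amplitude = rep(1, n_icns), coupling = rep(1, n_icns)),
       EC = list(amplitude = ec_amp, coupling = rep(1, n_icns)))
}

#' Specification of a synthetic resting-state cohort
#'
#' Collects and validates every knob of the synthetic-data generator: the
#' planted micro-states (synchrony-group partitions), phase-coupling
#' concentration, per-state amplitude profiles, condition effects, state
#' dwell time, motion-spike rate and RNG seed. The defaults are the study
#' conditions used throughout the package's tests: 10 subjects x 2
#' conditions, 10 networks, 240 volumes at TR = 2 s in the 0.01-0.08 Hz
#' band, 4 planted states with kappa = 20, a 1.5x EC amplitude effect on
#' the sensorimotor and auditory networks, 60-sample dwell blocks and on
#' average 2 motion spikes per session.
#'
#' @param n_subjects subjects in the cohort (>= 2 for group statistics).
#' @param n_icns networks per session.
#' @param n_volumes samples per session.
#' @param tr sampling interval, seconds.
#' @param band pass band `(low_hz, high_hz)` of the planted oscillations.
#' @param n_states number of planted micro-states.
#' @param state_partitions per-state synchrony-group partitions; see
#'   [default_state_partitions()].
#' @param coupling_kappa phase-noise concentration: each network's phase is
#'   its group phase plus wrapped-normal noise with standard deviation
#'   `1/sqrt(kappa)`, so higher kappa means tighter locking.
#' @param amplitude_profiles `n_states` x `n_icns` positive matrix of mean
#'   envelope amplitudes.
#' @param condition_effects per-condition multiplicative amplitude and
#'   coupling factors; see [default_condition_effects()].
#' @param dwell_min state dwell-block length in samples; must be at least
#'   `window_m + 1` so a window-majority state label is unambiguous.
#' @param motion_spike_rate expected motion spikes per session (Poisson).
#' @param noise_snr amplitude-to-noise ratio of the additive observation
#'   noise (noise sd = planted envelope / `noise_snr`).
#' @param phase_drift_sd per-sample standard deviation (radians) of the slow
#'   random phase drift shared within a synchrony group; keeps group phases
#'   from being perfectly periodic while leaving the signal narrowband.
#' @param window_m analysis window parameter used for ground-truth window
#'   labels and the dwell-time validity check.
#' @param seed cohort-level RNG seed.
#' @return validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 10L,
                           n_icns = 10L,
                           n_volumes = 240L,
                           tr = 2,
                           band = c(0.01, 0.08),
                           n_states = 4L,
                           state_partitions = default_state_partitions(n_states, n_icns),
                           coupling_kappa = 20,
                           amplitude_profiles = default_amplitude_profiles(n_states, n_icns),
                           condition_effects = default_condition_effects(n_icns),
                           dwell_min = 60L,
                           motion_spike_rate = 2,
                           noise_snr = 10,
                           phase_drift_sd = 0.15,
                           window_m = 22L,
                           seed = 42L) {
  if (!is_count(n_subjects)) stopf("n_subjects must be a positive integer")
  if (!is_count(n_icns, 2) || !is_count(n_volumes, 2) || !is_count(n_states))
    stopf("n_icns, n_volumes and n_states must be positive integers")
  if (!(band[1L] > 0 && band[1L] < band[2L] && band[2L] < 1 / (2 * tr)))
    stopf("band must satisfy 0 < low < high < Nyquist = %g Hz", 1 / (2 * tr))
  if (!is_count(dwell_min, window_m + 1L))
    stopf("dwell_min (%d) must be at least the window span m + 1 = %d samples",
          dwell_min, window_m + 1L)
  if (coupling_kappa <= 0) stopf("coupling_kappa must be positive")
  amplitude_profiles <- as.matrix(amplitude_profiles)
  if (!all(dim(amplitude_profiles) == c(n_states, n_icns)))
    stopf("amplitude_profiles must be %d x %d", n_states, n_icns)
  if (any(amplitude_profiles <= 0)) stopf("amplitude profiles must be positive")
  if (length(state_partitions) != n_states)
    stopf("need one partition per state")
  for (s in seq_len(n_states)) {
    cover <- sort(unlist(state_partitions[[s]]))
    if (!identical(as.integer(cover), seq_len(n_icns)))
      stopf("state %d partition must cover each of the %d networks exactly once",
            s, n_icns)
  }
  for (cond in names(condition_effects)) {
    ce <- condition_effects[[cond]]
    if (length(ce$amplitude) != n_icns || length(ce$coupling) != n_icns)
      stopf("condition_effects$%s factors must have length %d", cond, n_icns)
    if (any(ce$amplitude <= 0) || any(ce$coupling <= 0))
      stopf("condition factors must be positive")
  }
  if (motion_spike_rate < 0) stopf("motion_spike_rate must be >= 0")
  if (noise_snr <= 0) stopf("noise_snr must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_icns = as.integer(n_icns),
                 n_volumes = as.integer(n_volumes), tr = tr, band = band,
                 n_states = as.integer(n_states),
                 state_partitions = state_partitions,
                 coupling_kappa = coupling_kappa,
                 amplitude_profiles = amplitude_profiles,
                 condition_effects = condition_effects,
                 dwell_min = as.integer(dwell_min),
                 motion_spike_rate = motion_spike_rate,
                 noise_snr = noise_snr,
                 phase_drift_sd = phase_drift_sd,
                 window_m = as.integer(window_m),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# planted EC-vs-EO differences implied by the condition effects
planted_differences <- function(spec) {
  icn <- default_icn_names(spec$n_icns)
  ce <- spec$condition_effects
  ratio <- ce$EC$amplitude / ce$EO$amplitude
  hit <- which(ratio != 1)
  if (length(hit) == 0L)
    return(data.frame(state = integer(), feature = character(),
                      direction = character()))
  out <- expand.grid(state = seq_len(spec$n_states), k = hit)
  data.frame(state = out$state,
             feature = paste0("dAMP_", icn[out$k]),
             direction = ifelse(ratio[out$k] > 1, "EC>EO", "EC<EO"))
}

#' Generate one synthetic resting-state session
#'
#' Each network time course is a band-limited oscillation
#' `A_k(t) * cos(theta_g(t) + eps_k(t)) + noise`: networks in the same
#' planted synchrony group share the group phase `theta_g` (a constant
#' within-band frequency per dwell block, integrated over time, plus a slow
#' shared drift, re-randomized at every state switch so no phase carries
#' across states), `eps_k` is wrapped-normal phase noise with concentration
#' `coupling_kappa` times the condition's coupling factor, and the envelope
#' `A_k` follows the state's amplitude profile times the condition's
#' amplitude factor. Observation noise is white with sd `A_k/noise_snr`, so
#' the planted envelope — not the noise floor — carries any condition
#' effect. State switches occur only at dwell-block boundaries. Motion
#' traces are smooth sub-threshold sinusoidal drift plus step displacements
#' above the 0.5 mm FD threshold at the planted spike samples.
#'
#' @param spec a [synthetic_spec()].
#' @param condition condition label; must name an entry of
#'   `spec$condition_effects`.
#' @param seed session RNG seed.
#' @param subject subject identifier attached to the session.
#' @return list with components `tcs` (a [time_course_set()]), `motion`
#'   (T x 6 matrix) and `truth` (ground truth: `state_sequence`,
#'   `window_state`, `artifact_samples`, `condition`,
#'   `planted_differences`).
#' @export
generate_session <- function(spec, condition, seed,
                             subject = NA_character_) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!condition %in% names(spec$condition_effects))
    stopf("unknown condition '%s' (spec defines: %s)", condition,
          paste(names(spec$condition_effects), collapse = ", "))
  ce <- spec$condition_effects[[condition]]
  tt <- spec$n_volumes
  k <- spec$n_icns
  icn <- default_icn_names(k)

  with_seed(seed, {
    # --- state block sequence (uniform walk, no immediate repeats) -------
    n_blocks <- ceiling(tt / spec$dwell_min)
    states <- integer(n_blocks)
    states[1L] <- sample.int(spec$n_states, 1L)
    if (n_blocks > 1L) for (b in 2:n_blocks) {
      states[b] <- if (spec$n_states == 1L) 1L else
        sample(setdiff(seq_len(spec$n_states), states[b - 1L]), 1L)
    }
    state_seq <- rep(states, each = spec$dwell_min)[seq_len(tt)]
    block_of <- rep(seq_len(n_blocks), each = spec$dwell_min)[seq_len(tt)]

    # --- phases: per block, per synchrony group --------------------------
    # Group frequencies are drawn stratified across the band (one jittered
    # sub-band per group, randomly assigned), so distinct groups oscillate
    # at distinct frequencies and planted asynchrony is identifiable at the
    # window scale; a near-tie in frequency would otherwise make two
    # independent groups look phase-locked for a whole dwell block.
    phase <- matrix(0, k, tt)
    for (b in seq_len(n_blocks)) {
      idx <- which(block_of == b)
      len <- length(idx)
      part <- spec$state_partitions[[states[b]]]
      n_g <- length(part)
      strat_w <- diff(spec$band) / n_g
      freqs <- sample(spec$band[1L] + (seq_len(n_g) - 1L) * strat_w +
                        strat_w * stats::runif(n_g, 0.25, 0.75))
      for (gi in seq_along(part)) {
        g <- part[[gi]]
        f <- freqs[gi]
        th0 <- stats::runif(1L, -pi, pi)
        drift <- cumsum(stats::rnorm(len, 0, spec$phase_drift_sd))
        theta <- th0 + 2 * pi * f * (seq_len(len) - 1L) * spec$tr + drift
        for (kk in g) {
          kap <- spec$coupling_kappa * ce$coupling[kk]
          phase[kk, idx] <- theta + stats::rnorm(len, 0, 1 / sqrt(kap))
        }
      }
    }

    # --- envelopes and observed series -----------------------------------
    amp <- t(spec$amplitude_profiles[state_seq, , drop = FALSE]) *
      ce$amplitude
    x <- amp * cos(phase) +
      matrix(stats::rnorm(k * tt), k, tt) * amp / spec$noise_snr
    rownames(x) <- icn

    # --- motion: smooth drift + planted step spikes -----------------------
    t_sec <- (seq_len(tt) - 1L) * spec$tr
    motion <- vapply(1:6, function(j) {
      a <- if (j <= 3) stats::runif(1L, 0.01, 0.04) else
        stats::runif(1L, 2e-4, 8e-4)
      fj <- stats::runif(1L, 0.003, 0.015)
      a * sin(2 * pi * fj * t_sec + stats::runif(1L, 0, 2 * pi)) +
        stats::rnorm(tt, 0, a / 20)
    }, numeric(tt))
    n_spikes <- stats::rpois(1L, spec$motion_spike_rate)
    spikes <- integer(0)
    if (n_spikes > 0L && tt > 4L) {
      spikes <- sort(sample(3:(tt - 2L), min(n_spikes, tt %/% 10L)))
      for (s in spikes) {
        jump <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.7, 1.2)
        motion[s:tt, 1L] <- motion[s:tt, 1L] + jump
      }
    }

    # --- ground truth ------------------------------------------------------
    wins <- sliding_windows(tt, m = spec$window_m, step = 1L)
    window_state <- vapply(seq_len(nrow(wins)), function(i) {
      s <- state_seq[wins$start[i]:wins$end[i]]
      as.integer(names(which.max(table(s))))
    }, integer(1L))

    list(tcs = time_course_set(x, tr = spec$tr, subject = subject,
                               condition = condition),
         motion = motion,
         truth = list(state_sequence = state_seq,
                      window_state = window_state,
                      artifact_samples = spikes,
                      condition = condition,
                      planted_differences = planted_differences(spec)))
  })
}

#' Generate a synthetic two-condition cohort
#'
#' One eyes-open and one eyes-closed session per subject, with
#' subject-and-condition seeds derived deterministically from `spec$seed`,
#' so identical specs give bit-identical cohorts. Planted differences are
#' identical across subjects.
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `synthetic_cohort`: list of sessions, each as
#'   returned by [generate_session()] plus `subject` and `condition`
#'   fields, with the spec attached as attribute `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_subjects < 2L)
    stopf("group statistics need at least 2 subjects, got %d", spec$n_subjects)
  conds <- names(spec$condition_effects)
  seeds <- with_seed(spec$seed,
    matrix(sample.int(.Machine$integer.max - 1L,
                      spec$n_subjects * length(conds)),
           spec$n_subjects, length(conds)))
  sessions <- list()
  for (i in seq_len(spec$n_subjects)) {
    subj <- sprintf("sub%02d", i)
    for (ci in seq_along(conds)) {
      s <- generate_session(spec, conds[ci], seed = seeds[i, ci],
                            subject = subj)
      s$subject <- subj
      s$condition <- conds[ci]
      sessions[[length(sessions) + 1L]] <- s
    }
  }
  structure(sessions, class = "synthetic_cohort", spec = spec)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("synthetic_cohort: %d sessions (%d subjects), %d networks x %d samples, %d planted states\n",
              length(x), spec$n_subjects, spec$n_icns, spec$n_volumes,
              spec$n_states))
  invisible(x)
}

#' Write a synthetic cohort to plain-text files
#'
#' Per session: the time courses as tab-separated text
#' (`<subject>_<condition>_tcs.tsv`, see [write_timecourses()]), the motion
#' parameters as 6-column whitespace-delimited text (`..._motion.par`) and
#' the ground truth as JSON (`..._truth.json`).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file prefixes written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefixes <- character(0)
  for (s in cohort) {
    prefix <- file.path(dir, sprintf("%s_%s", s$subject, s$condition))
    write_timecourses(s$tcs, paste0(prefix, "_tcs.tsv"))
    utils::write.table(s$motion, paste0(prefix, "_motion.par"),
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(s$truth, paste0(prefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    prefixes <- c(prefixes, prefix)
  }
  invisible(prefixes)
}
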