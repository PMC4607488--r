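test_that("identical spec and seed give bit-identical output", {
  spec <- tiny_spec()
  s1 <- generate_session(spec, "EO", seed = 5)
  s2 <- generate_session(spec, "EO", seed = 5)
  expect_identical(s1, s2)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
})

test_that("cohorts have one EO and one EC session per subject", {
  co <- generate_cohort(tiny_spec(n_subjects = 5))
  expect_length(co, 10)
  conds <- vapply(co, `[[`, character(1), "condition")
  expect_equal(sum(conds == "EO"), 5)
  expect_equal(sum(conds == "EC"), 5)
  subj <- vapply(co, `[[`, character(1), "subject")
  expect_equal(length(unique(subj)), 5)
})

test_that("invalid specs are rejected", {
  expect_error(generate_cohort(tiny_spec(n_subjects = 1)), "at least 2")
  expect_error(tiny_spec(dwell_min = 20), "window span")
  expect_error(tiny_spec(amplitude_profiles = -default_amplitude_profiles(2, 10)),
               "positive")
  bad_parts <- list(list(1:10), list(1:4, 4:10))  # network 4 twice
  expect_error(tiny_spec(state_partitions = bad_parts), "exactly once")
  expect_error(tiny_spec(band = c(0.01, 0.3)), "Nyquist")
  expect_error(generate_session(tiny_spec(), "REM", seed = 1),
               "unknown condition")
})

test_that("infinite coupling concentration gives perfect within-group dPS", {
  spec <- tiny_spec(n_states = 1,
                    state_partitions = list(list(1:10)),
                    amplitude_profiles = default_amplitude_profiles(1, 10),
                    coupling_kappa = 1e9, noise_snr = 1e6)
  s <- generate_session(spec, "EO", seed = 31)
  f <- windowed_features(s$tcs)
  expect_true(all(f$dps > 0.999))
})

test_that("cross-group dPS matches a Monte-Carlo oracle of the phase process", {
  spec <- synthetic_spec(n_subjects = 4, n_volumes = 240, dwell_min = 40,
                         n_states = 2,
                         state_partitions = list(list(1:10),
                                                 list(1:5, 6:10)),
                         amplitude_profiles = default_amplitude_profiles(2, 10),
                         condition_effects = null_condition_effects(),
                         seed = 33)
  co <- generate_cohort(spec)
  cross <- within <- c()
  for (s in co) {
    f <- windowed_features(s$tcs)
    ws <- truth_window_states(s, 240, 22, 1)
    pure <- vapply(seq_len(nrow(f$windows)), function(i)
      length(unique(s$truth$state_sequence[
        f$windows$start[i]:f$windows$end[i]])) == 1, logical(1))
    pr <- icn_pairs(f$icn_names)
    is_cross <- (pr$i <= 5) != (pr$j <= 5)
    cross <- c(cross, as.numeric(f$dps[pure & ws == 2, is_cross]))
    within <- c(within, as.numeric(f$dps[pure & ws == 2, !is_cross]))
  }
  # oracle: simulate the generator's cross-group phase-difference process
  set.seed(34)
  kappa <- spec$coupling_kappa
  n <- 23
  oracle <- mean(replicate(20000, {
    w <- diff(spec$band) / 2
    f1 <- spec$band[1] + w * runif(1, 0.25, 0.75)
    f2 <- spec$band[1] + w + w * runif(1, 0.25, 0.75)
    d <- runif(1, -pi, pi) + 2 * pi * (f1 - f2) * (0:(n - 1)) * spec$tr +
      cumsum(rnorm(n, 0, spec$phase_drift_sd)) -
      cumsum(rnorm(n, 0, spec$phase_drift_sd)) +
      rnorm(n, 0, sqrt(2 / kappa))
    sqrt(mean(cos(d))^2 + mean(sin(d))^2)
  }))
  # the analytic-signal phase estimate smooths the iid phase noise a little,
  # so the measured synchrony sits slightly above the planted-phase oracle
  expect_lt(abs(mean(cross) - oracle), 0.03)
  expect_gt(mean(within), 0.9)
  expect_gt(mean(within), mean(cross) + 0.4)
})

test_that("planted EC amplitude effect raises pooled dAMP of the target ICNs", {
  co <- generate_cohort(tiny_spec(n_subjects = 4))
  damp <- lapply(co, function(s) {
    f <- windowed_features(s$tcs)
    colMeans(f$damp)
  })
  conds <- vapply(co, `[[`, character(1), "condition")
  ec <- colMeans(do.call(rbind, damp[conds == "EC"]))
  eo <- colMeans(do.call(rbind, damp[conds == "EO"]))
  expect_gt(ec["SMN"] / eo["SMN"], 1.2)
  expect_gt(ec["AN"] / eo["AN"], 1.2)
  expect_equal(unname(ec[c("MVN", "DMN", "CBN")] / eo[c("MVN", "DMN", "CBN")]),
               rep(1, 3), tolerance = 0.1)
  pd <- co[[1]]$truth$planted_differences
  expect_setequal(unique(pd$feature), c("dAMP_SMN", "dAMP_AN"))
  expect_true(all(pd$direction == "EC>EO"))
})

test_that("null condition effects plant nothing and t-tests stay calibrated", {
  # calibration checked on the amplitude family, whose windows are driven by
  # independent observation noise; windows are taken one per dwell block
  ps <- c()
  for (rep in 1:20) {
    spec <- synthetic_spec(n_subjects = 4, n_volumes = 160, dwell_min = 40,
                           n_states = 2,
                           state_partitions = default_state_partitions(2, 10),
                           amplitude_profiles = default_amplitude_profiles(2, 10),
                           condition_effects = null_condition_effects(),
                           seed = 4000 + rep)
    co <- generate_cohort(spec)
    expect_equal(nrow(co[[1]]$truth$planted_differences), 0)
    feats <- lapply(co, function(s) windowed_features(s$tcs, 22, step = 40))
    inst <- concatenate_features(feats)
    truth <- unlist(lapply(co, function(s)
      s$truth$state_sequence[sliding_windows(160, 22, 40)$start]))
    cmp <- suppressWarnings(compare_conditions(inst, truth))
    ps <- c(ps, cmp$p[cmp$family == "dAMP"])
  }
  n <- length(ps)
  expect_gte(n, 200)
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("windowed dAMP tracks the planted envelopes within 5 percent", {
  spec <- tiny_spec(motion_spike_rate = 0)
  s <- generate_session(spec, "EC", seed = 35)
  f <- windowed_features(s$tcs)
  ce <- spec$condition_effects$EC$amplitude
  # keep a 5-sample guard band from state switches: the analytic envelope
  # smears amplitude steps over a few samples
  pure <- vapply(seq_len(nrow(f$windows)), function(i) {
    a <- f$windows$start[i]; b <- f$windows$end[i]
    a > 10 && b < 110 &&
      length(unique(s$truth$state_sequence[(a - 5):(b + 5)])) == 1
  }, logical(1))
  ws <- truth_window_states(s, 120, 22, 1)
  for (st in unique(ws[pure])) {
    got <- colMeans(f$damp[pure & ws == st, , drop = FALSE])
    planted <- spec$amplitude_profiles[st, ] * ce
    expect_equal(unname(got / planted), rep(1, 10), tolerance = 0.05)
  }
})

test_that("motion spikes are detectable and censored exactly", {
  spec <- tiny_spec(motion_spike_rate = 3)
  found <- 0
  for (seed in 41:46) {
    s <- generate_session(spec, "EO", seed = seed)
    fd <- framewise_displacement(s$motion)
    expect_equal(which(fd > 0.5), s$truth$artifact_samples)
    if (length(s$truth$artifact_samples) > 0) {
      found <- found + 1
      w <- sliding_windows(120, 22)
      cm <- censor_session(s$motion, w)
      truth_marked <- rep(FALSE, 120)
      for (a in s$truth$artifact_samples)
        truth_marked[max(1, a - 1):min(120, a + 1)] <- TRUE
      expect_equal(cm$retained_windows, oracle_retained(w, truth_marked))
    }
  }
  expect_gt(found, 0)
})

test_that("state sequence switches only at dwell boundaries", {
  spec <- tiny_spec(n_states = 4,
                    state_partitions = default_state_partitions(4, 10),
                    amplitude_profiles = default_amplitude_profiles(4, 10))
  s <- generate_session(spec, "EO", seed = 51)
  seqs <- s$truth$state_sequence
  expect_length(seqs, 120)
  switches <- which(diff(seqs) != 0)
  expect_true(all(switches %% spec$dwell_min == 0))
  expect_length(s$truth$window_state, 120 - 22)
})

test_that("dPS increases monotonically with the coupling concentration", {
  kappas <- c(5, 10, 20, 40, 80)
  means <- vapply(kappas, function(k) {
    spec <- tiny_spec(n_states = 1, state_partitions = list(list(1:10)),
                      amplitude_profiles = default_amplitude_profiles(1, 10),
                      coupling_kappa = k, motion_spike_rate = 0)
    s <- generate_session(spec, "EO", seed = 61)
    mean(windowed_features(s$tcs)$dps)
  }, numeric(1))
  expect_equal(cor(means, kappas, method = "spearman"), 1)
})

test_that("cohorts round-trip through the plain-text writers", {
  co <- generate_cohort(tiny_spec(n_subjects = 2))
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  s <- co[[1]]
  prefix <- file.path(dir, sprintf("%s_%s", s$subject, s$condition))
  tcs2 <- read_timecourses(paste0(prefix, "_tcs.tsv"), tr = 2)
  expect_equal(tcs2$data, s$tcs$data, tolerance = 1e-6)
  mo2 <- read_motion(paste0(prefix, "_motion.par"))
  expect_equal(mo2, s$motion, tolerance = 1e-6)
  truth <- jsonlite::read_json(paste0(prefix, "_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$state_sequence, s$truth$state_sequence)
  unlink(dir, recursive = TRUE)
})
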