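#' Pipeline run configuration
#'
#' Collects and validates every analysis parameter with the conventional
#' defaults: 22-sample (44 s at TR = 2 s) windows advancing 1 sample,
#' 0.01-0.08 Hz band, FD threshold 0.5 mm, synchrony threshold 0.5,
#' significance level 0.001 on FDR-corrected q-values, cluster-number
#' detection from 200-instance draws, and a window sweep of 13..40 samples
#' in steps of 3 for the robustness harness.
#'
#' @param window_m window length parameter in samples.
#' @param step window step in samples.
#' @param tr sampling interval, seconds.
#' @param band temporal pass band in Hz.
#' @param fd_thresh framewise-displacement threshold in mm.
#' @param tau synchrony threshold for graph binarization.
#' @param alpha significance level on FDR-adjusted q-values.
#' @param k number of micro-states, or `"auto"` to detect.
#' @param draw_size,n_sims,k_max cluster-number detection parameters.
#' @param window_sweep window lengths for [robustness_sweep()].
#' @param head_radius rotation-to-arc-length radius, mm.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return validated list of class `dynsync_config`.
#' @export
run_config <- function(window_m = 22L, step = 1L, tr = 2,
                       band = c(0.01, 0.08), fd_thresh = 0.5, tau = 0.5,
                       alpha = 0.001, k = "auto", draw_size = 200L,
                       n_sims = 1000L, k_max = 9L,
                       window_sweep = seq(13L, 40L, by = 3L),
                       head_radius = 50, seed = 1L) {
  if (!is_count(window_m) || !is_count(step))
    stopf("window_m and step must be positive integers")
  if (!(band[1L] > 0 && band[1L] < band[2L] && band[2L] < 1 / (2 * tr)))
    stopf("infeasible band for tr = %g s", tr)
  if (fd_thresh <= 0 || tau < 0 || tau > 1 || alpha <= 0 || alpha >= 1)
    stopf("thresholds out of range")
  if (!identical(k, "auto") && !is_count(k))
    stopf("k must be \"auto\" or a positive integer")
  structure(list(window_m = as.integer(window_m), step = as.integer(step),
                 tr = tr, band = band, fd_thresh = fd_thresh, tau = tau,
                 alpha = alpha, k = k, draw_size = as.integer(draw_size),
                 n_sims = as.integer(n_sims), k_max = as.integer(k_max),
                 window_sweep = as.integer(window_sweep),
                 head_radius = head_radius, seed = as.integer(seed)),
            class = "dynsync_config")
}

session_features <- function(cohort, config, m = config$window_m,
                             step = config$step) {
  feats <- lapply(cohort, function(s)
    windowed_features(s$tcs, m = m, step = step))
  retained <- lapply(seq_along(cohort), function(i) {
    cm <- censor_session(cohort[[i]]$motion, feats[[i]]$windows,
                         fd_thresh = config$fd_thresh,
                         head_radius = config$head_radius)
    cm$retained_windows
  })
  list(features = feats, retained = retained)
}

#' Run the full micro-state analysis on a cohort
#'
#' Orchestrates the end-to-end pipeline: per-session sliding-window
#' synchrony/amplitude features, FD-based motion censoring, cross-session
#' concatenation, cluster-number detection (unless `config$k` is fixed),
#' Ward clustering, state summaries, condition contrasts of features and
#' of amplitude-strength coupling, and per-window graph efficiency.
#' Deterministic given `config$seed`.
#'
#' @param cohort a list of sessions, each with elements `tcs`
#'   (a [time_course_set()]) and `motion` (T x 6 matrix) — e.g. a
#'   [generate_cohort()] result.
#' @param config a [run_config()].
#' @param ref_icn reference network for the coupling analyses.
#' @param out_dir optional directory; when given, all tabular results plus
#'   a JSON run manifest are written there.
#' @return list of class `dynsync_run` with elements `instances`, `model`,
#'   `k_detection`, `comparisons`, `amp_strength`, `amp_ps`, `efficiency`
#'   (per-instance values and state contrast) and `manifest`.
#' @export
run_pipeline <- function(cohort, config = run_config(), ref_icn = "DMN",
                         out_dir = NULL) {
  stopifnot(inherits(config, "dynsync_config"))
  sf <- session_features(cohort, config)
  instances <- concatenate_features(sf$features, sf$retained)
  if (nrow(instances$features) == 0L)
    stopf("censoring removed every window; nothing to analyse")

  k_detection <- NULL
  k <- config$k
  if (identical(k, "auto")) {
    k_detection <- detect_cluster_number(
      instances, draw_size = config$draw_size, n_sims = config$n_sims,
      k_max = config$k_max, seed = config$seed)
    k <- k_detection$k
  }
  cl <- hierarchical_cluster(instances, k)
  model <- summarize_states(instances, cl$assignments, tree = cl$tree)

  comparisons <- compare_conditions(instances, cl$assignments,
                                    alpha = config$alpha)
  if (!ref_icn %in% instances$icn_names) ref_icn <- instances$icn_names[1L]
  amp_strength <- amplitude_strength_relationship(instances,
                                                  cl$assignments,
                                                  icn = ref_icn)
  amp_ps <- amplitude_ps_contrast(instances, cl$assignments,
                                  ref_icn = ref_icn, alpha = config$alpha)
  eff <- instance_efficiencies(instances, tau = config$tau)
  eff_contrast <- efficiency_contrast(eff, cl$assignments,
                                      instances$meta$condition)

  manifest <- list(
    package = "dynsync",
    version = as.character(utils::packageVersion("dynsync")),
    config = unclass(config),
    n_sessions = length(cohort),
    n_instances = nrow(instances$features),
    n_censored = sum(vapply(sf$features, function(f) nrow(f$windows),
                            integer(1L))) - nrow(instances$features),
    k = k)

  res <- structure(list(instances = instances, model = model,
                        k_detection = k_detection,
                        comparisons = comparisons,
                        amp_strength = amp_strength, amp_ps = amp_ps,
                        efficiency = list(values = eff,
                                          contrast = eff_contrast),
                        manifest = manifest),
                   class = "dynsync_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cbind(res$instances$meta, state = res$model$assignments),
     "assignments.tsv")
  for (s in seq_len(res$model$k))
    utils::write.table(round(res$model$centroids[[s]], 6),
                       file.path(out_dir, sprintf("centroid_state%d.tsv", s)),
                       sep = "\t", quote = FALSE)
  wt(data.frame(state = rownames(res$model$fractions),
                res$model$fractions, check.names = FALSE), "fractions.tsv")
  wt(res$comparisons, "comparisons.tsv")
  if (!is.null(res$amp_strength$correlations))
    wt(res$amp_strength$correlations, "amp_strength_correlations.tsv")
  if (!is.null(res$amp_strength$contrasts))
    wt(res$amp_strength$contrasts, "amp_strength_contrasts.tsv")
  if (!is.null(res$amp_ps$table)) wt(res$amp_ps$table, "amp_ps_contrasts.tsv")
  wt(data.frame(res$instances$meta, efficiency = res$efficiency$values),
     "efficiency.tsv")
  if (!is.null(res$efficiency$contrast))
    wt(res$efficiency$contrast, "efficiency_contrast.tsv")
  if (!is.null(res$model$tree))
    wt(data.frame(step = seq_len(nrow(res$model$tree$merge)),
                  left = res$model$tree$merge[, 1L],
                  right = res$model$tree$merge[, 2L],
                  height = res$model$tree$height), "linkage.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.dynsync_run <- function(x, ...) {
  cat(sprintf("dynsync_run: %d instances, k = %d states\n",
              nrow(x$instances$features), x$model$k))
  print(round(x$model$fractions, 1))
  ns <- sum(x$comparisons$significant)
  cat(sprintf("%d significant condition contrasts at q < %g\n", ns,
              x$manifest$config$alpha))
  invisible(x)
}

#' Sliding-window-size robustness sweep
#'
#' Refits the windowed features and clustering for every window length in
#' `config$window_sweep`, matches the resulting states to the reference
#' model (fitted at `reference_m`) and reports the matched-state centroid
#' correlations — the robustness curves of micro-state topology against
#' window length.
#'
#' @param cohort session list as for [run_pipeline()].
#' @param config a [run_config()]; `config$k` should normally be fixed to
#'   the reference model's k (it is reused for every window length).
#' @param reference_m reference window length in samples.
#' @return list with `curves` (data.frame m, state_ref, state_m, r) and
#'   `reference` (the reference `microstate_model`).
#' @export
robustness_sweep <- function(cohort, config = run_config(),
                             reference_m = 22L) {
  stopifnot(inherits(config, "dynsync_config"))
  t_len <- ncol(cohort[[1L]]$tcs$data)
  fit_at <- function(m, k) {
    sf <- session_features(cohort, config, m = m)
    inst <- concatenate_features(sf$features, sf$retained)
    cl <- hierarchical_cluster(inst, k)
    summarize_states(inst, cl$assignments)
  }
  sfr <- session_features(cohort, config, m = reference_m)
  inst_ref <- concatenate_features(sfr$features, sfr$retained)
  k <- config$k
  if (identical(k, "auto")) {
    k <- detect_cluster_number(inst_ref, draw_size = config$draw_size,
                               n_sims = config$n_sims,
                               k_max = config$k_max,
                               seed = config$seed)$k
  }
  cl_ref <- hierarchical_cluster(inst_ref, k)
  reference <- summarize_states(inst_ref, cl_ref$assignments)

  out <- list()
  for (m in config$window_sweep) {
    if (m >= t_len) {
      warnf("window length %d >= series length %d; skipped", m, t_len)
      next
    }
    model_m <- if (m == reference_m) reference else fit_at(m, k)
    mt <- match_states(reference, model_m)
    out[[length(out) + 1L]] <- data.frame(
      m = m, state_ref = mt$pairs$state_a, state_m = mt$pairs$state_b,
      r = mt$pairs$r)
  }
  list(curves = do.call(rbind, c(out, list(make.row.names = FALSE))),
       reference = reference)
}
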