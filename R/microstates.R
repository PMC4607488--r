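#' Concatenate censored windowed features across sessions
#'
#' Stacks the retained windows of every session into the instance matrix
#' used for unsupervised learning: rows in (subject, session, window)
#' order, columns the row-major upper-triangle dPS pairs. The per-window
#' amplitudes are carried alongside as aligned metadata (clustering itself
#' uses only the synchrony features).
#'
#' @param features_list list of [windowed_features()] objects.
#' @param retained optional list (same length) of retained window indices
#'   per session, e.g. from [censor_windows()]; `NULL` keeps everything.
#' @return object of class `instance_matrix`: list with `features` (N x P
#'   dPS matrix), `damp` (N x K), `meta` (data.frame subject, condition,
#'   window), `icn_names`, `pair_names`.
#' @export
concatenate_features <- function(features_list, retained = NULL) {
  stopifnot(length(features_list) >= 1L)
  icn <- features_list[[1L]]$icn_names
  for (f in features_list)
    if (!identical(f$icn_names, icn))
      stopf("sessions disagree on network names; cannot concatenate")
  if (is.null(retained))
    retained <- lapply(features_list, function(f) f$windows$index)
  stopifnot(length(retained) == length(features_list))
  rows <- vector("list", length(features_list))
  for (i in seq_along(features_list)) {
    f <- features_list[[i]]
    keep <- match(retained[[i]], f$windows$index)
    if (length(keep) == 0L || anyNA(keep)) {
      if (length(retained[[i]]) == 0L) {
        warnf("session %s/%s contributes no retained windows",
              f$subject, f$condition)
        keep <- integer(0)
      } else stopf("retained window ids not found in session %d", i)
    }
    rows[[i]] <- list(
      features = f$dps[keep, , drop = FALSE],
      damp = f$damp[keep, , drop = FALSE],
      meta = data.frame(subject = rep(f$subject, length(keep)),
                        condition = rep(f$condition, length(keep)),
                        window = f$windows$index[keep]))
  }
  structure(list(
    features = do.call(rbind, lapply(rows, `[[`, "features")),
    damp = do.call(rbind, lapply(rows, `[[`, "damp")),
    meta = do.call(rbind, c(lapply(rows, `[[`, "meta"),
                            list(make.row.names = FALSE))),
    icn_names = icn,
    pair_names = colnames(features_list[[1L]]$dps)),
    class = "instance_matrix")
}

#' @export
print.instance_matrix <- function(x, ...) {
  cat(sprintf("instance_matrix: %d instances x %d synchrony features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s: %d", names(table(x$meta$condition)),
                            table(x$meta$condition)), collapse = ", ")))
  invisible(x)
}

as_feature_matrix <- function(x) {
  if (inherits(x, "instance_matrix")) x$features else as.matrix(x)
}

#' Detect the number of micro-states by repeated Gaussian-mixture fits
#'
#' Draws `draw_size` instances without replacement, fits Gaussian mixture
#' models with 1..`k_max` components over spherical, diagonal and full
#' covariance families, and selects the component count by BIC; the draw is
#' repeated `n_sims` times and the histogram of per-draw optima is
#' returned. The consensus `k` is the histogram mode (smallest value on
#' ties), with the median reported alongside.
#'
#' @param x an `instance_matrix` or plain numeric matrix of instances.
#' @param draw_size instances per draw (capped at N).
#' @param n_sims number of repeated draws.
#' @param k_max largest number of components considered.
#' @param seed RNG seed for the draws.
#' @param models mclust covariance model names to consider.
#' @return list with `k` (modal optimum), `k_median`, `histogram` (counts
#'   for 1..k_max) and `draws` (per-simulation optima).
#' @export
detect_cluster_number <- function(x, draw_size = 200L, n_sims = 1000L,
                                  k_max = 9L, seed = NULL,
                                  models = c("EII", "VII", "EEI", "VVI",
                                             "EEE", "VVV")) {
  x <- as_feature_matrix(x)
  if (nrow(x) < 2L) stopf("need at least 2 instances")
  if (!is_count(k_max, 2)) stopf("k_max must be >= 2")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stopf("degenerate features with zero variance: %s",
          paste(colnames(x)[sds == 0] %||% which(sds == 0), collapse = ", "))
  n_draw <- min(draw_size, nrow(x))
  draws <- with_seed(seed, vapply(seq_len(n_sims), function(s) {
    sub <- x[sample.int(nrow(x), n_draw), , drop = FALSE]
    bic <- tryCatch(
      mclust::mclustBIC(sub, G = seq_len(k_max), modelNames = models,
                        verbose = FALSE),
      error = function(e) NULL)
    if (is.null(bic) || all(is.na(bic))) return(NA_integer_)
    best <- which(bic == max(bic, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    as.integer(rownames(bic)[best[1L]])
  }, integer(1L)))
  ok <- draws[!is.na(draws)]
  if (length(ok) == 0L) stopf("no mixture fit succeeded")
  histogram <- tabulate(ok, nbins = k_max)
  names(histogram) <- seq_len(k_max)
  list(k = as.integer(which.max(histogram)),
       k_median = stats::median(ok),
       histogram = histogram,
       draws = draws)
}

#' Ward hierarchical clustering of synchrony instances
#'
#' Agglomerative clustering with Euclidean distances under Ward's
#' variance-minimizing criterion (`hclust` method `ward.D2`, i.e. merge
#' cost on squared distances), cut at `k` clusters.
#'
#' @param x an `instance_matrix` or numeric matrix.
#' @param k number of clusters, `1 <= k <= N`.
#' @return list with `assignments` (integer per instance), `tree` (the
#'   `hclust` merge history) and `k`.
#' @export
hierarchical_cluster <- function(x, k) {
  x <- as_feature_matrix(x)
  if (!is_count(k) || k > nrow(x))
    stopf("k must be an integer in 1..N = %d", nrow(x))
  tree <- stats::hclust(stats::dist(x), method = "ward.D2")
  list(assignments = unname(stats::cutree(tree, k = k)), tree = tree,
       k = as.integer(k))
}

#' Summarize micro-states from cluster assignments
#'
#' Per state: the centroid synchrony matrix (mean of member windows'
#' vectorized dPS, refolded symmetric with unit diagonal), the mean
#' amplitude profile, and the percentage of each condition's instances
#' spent in the state (summing to 100 within condition).
#'
#' @param instances an `instance_matrix` (amplitudes required for the
#'   amplitude profiles).
#' @param assignments integer state id per instance.
#' @param tree optional `hclust` merge history to attach.
#' @return object of class `microstate_model`.
#' @export
summarize_states <- function(instances, assignments, tree = NULL) {
  stopifnot(inherits(instances, "instance_matrix"))
  n <- nrow(instances$features)
  if (length(assignments) != n)
    stopf("assignments length %d != %d instances", length(assignments), n)
  k <- max(assignments)
  sizes <- tabulate(assignments, nbins = k)
  if (any(sizes == 0L))
    stopf("empty state(s) after assignment: %s",
          paste(which(sizes == 0L), collapse = ", "))
  cvec <- t(vapply(seq_len(k), function(s)
    colMeans(instances$features[assignments == s, , drop = FALSE]),
    numeric(ncol(instances$features))))
  rownames(cvec) <- paste0("state", seq_len(k))
  centroids <- lapply(seq_len(k), function(s)
    vector_to_dps(cvec[s, ], instances$icn_names))
  amp <- t(vapply(seq_len(k), function(s)
    colMeans(instances$damp[assignments == s, , drop = FALSE]),
    numeric(ncol(instances$damp))))
  dimnames(amp) <- list(paste0("state", seq_len(k)), instances$icn_names)
  conds <- sort(unique(instances$meta$condition))
  fractions <- vapply(conds, function(cc) {
    tab <- tabulate(assignments[instances$meta$condition == cc], nbins = k)
    100 * tab / sum(tab)
  }, numeric(k))
  fractions <- matrix(fractions, nrow = k,
                      dimnames = list(paste0("state", seq_len(k)), conds))
  structure(list(k = k, assignments = assignments,
                 centroid_vectors = cvec, centroids = centroids,
                 amplitude_profiles = amp, fractions = fractions,
                 sizes = sizes, icn_names = instances$icn_names,
                 pair_names = instances$pair_names, tree = tree),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("microstate_model: %d states over %d instances\n", x$k,
              length(x$assignments)))
  print(round(x$fractions, 1))
  invisible(x)
}

#' Threshold a centroid synchrony matrix
#'
#' Entries below `tau` are set to 0, others (and the diagonal) are kept —
#' the sparsified view used to display state topology.
#'
#' @param centroid synchrony matrix with values in [0, 1].
#' @param tau threshold in [0, 1].
#' @return thresholded matrix.
#' @export
threshold_centroid <- function(centroid, tau = 0.5) {
  if (tau < 0 || tau > 1) stopf("tau must lie in [0, 1]")
  if (any(centroid < 0 | centroid > 1)) stopf("centroid values must lie in [0, 1]")
  out <- centroid
  low <- out < tau
  if (!is.null(dim(out))) diag(low) <- FALSE
  out[low] <- 0
  out
}

all_injections <- function(k_from, k_to) {
  # all injective maps 1..k_from -> 1..k_to, as a matrix with one map per row
  rec <- function(chosen, avail) {
    if (length(chosen) == k_from) return(list(chosen))
    do.call(c, lapply(avail, function(a)
      rec(c(chosen, a), setdiff(avail, a))))
  }
  do.call(rbind, rec(integer(0), seq_len(k_to)))
}

#' Match micro-states between two fitted models
#'
#' One-to-one pairing of states maximizing the total Pearson correlation
#' between the vectorized centroid upper triangles (exact optimal
#' assignment by enumeration; state counts here are small). With unequal
#' state counts, min(k_a, k_b) states are paired and the rest reported
#' unmatched.
#'
#' @param model_a,model_b [summarize_states()] results on the same
#'   networks.
#' @return list with `pairs` (data.frame state_a, state_b, r), `total`
#'   (summed correlation) and `unmatched` (state ids of the larger model
#'   left unpaired).
#' @export
match_states <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "microstate_model"),
            inherits(model_b, "microstate_model"))
  if (!identical(model_a$icn_names, model_b$icn_names))
    stopf("models were fitted on different networks")
  ca <- model_a$centroid_vectors
  cb <- model_b$centroid_vectors
  rmat <- stats::cor(t(ca), t(cb))  # k_a x k_b
  ka <- nrow(ca); kb <- nrow(cb)
  flip <- ka > kb
  if (flip) rmat <- t(rmat)
  maps <- all_injections(min(ka, kb), max(ka, kb))
  scores <- apply(maps, 1L, function(mp)
    sum(rmat[cbind(seq_along(mp), mp)]))
  best <- maps[which.max(scores), ]
  pairs <- if (flip)
    data.frame(state_a = best, state_b = seq_along(best),
               r = rmat[cbind(seq_along(best), best)])
  else
    data.frame(state_a = seq_along(best), state_b = best,
               r = rmat[cbind(seq_along(best), best)])
  pairs <- pairs[order(pairs$state_a), , drop = FALSE]
  rownames(pairs) <- NULL
  unmatched <- if (flip) setdiff(seq_len(ka), pairs$state_a)
               else setdiff(seq_len(kb), pairs$state_b)
  list(pairs = pairs, total = max(scores), unmatched = unmatched)
}
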