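#' Node strength within one window's synchrony matrix
#'
#' Mean of the K-1 off-diagonal synchrony values in the network's row.
#'
#' @param dps_mat symmetric K x K synchrony matrix.
#' @param icn network index or row name.
#' @return scalar strength.
#' @export
node_strength <- function(dps_mat, icn) {
  if (is.character(icn)) icn <- match(icn, rownames(dps_mat))
  if (is.na(icn) || icn < 1L || icn > nrow(dps_mat))
    stopf("invalid network index")
  mean(dps_mat[icn, -icn])
}

#' Binarize a synchrony matrix into a window graph
#'
#' An edge is present iff dPS >= `tau`; the diagonal is cleared.
#'
#' @param dps_mat synchrony matrix with values in [0, 1].
#' @param tau threshold in [0, 1].
#' @return binary adjacency matrix.
#' @export
binarize <- function(dps_mat, tau = 0.5) {
  if (tau < 0 || tau > 1) stopf("tau must lie in [0, 1]")
  if (any(dps_mat < 0 | dps_mat > 1)) stopf("dPS values must lie in [0, 1]")
  adj <- (dps_mat >= tau) * 1
  diag(adj) <- 0
  adj
}

#' Global efficiency of a window graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' disconnected pairs contributing 0; 1 for the complete graph, 0 for the
#' empty one. Shortest paths are unit-length (binary graph).
#'
#' @param adj binary symmetric adjacency matrix with zero diagonal.
#' @return efficiency in [0, 1].
#' @export
global_efficiency <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  if (n < 2L) return(0)
  g <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected")
  d <- igraph::distances(g)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Per-window global efficiency over an instance matrix
#'
#' Binarizes each retained window's synchrony matrix at `tau` and computes
#' its global efficiency.
#'
#' @param instances an `instance_matrix`.
#' @param tau binarization threshold.
#' @return numeric vector, one efficiency per instance.
#' @export
instance_efficiencies <- function(instances, tau = 0.5) {
  stopifnot(inherits(instances, "instance_matrix"))
  vapply(seq_len(nrow(instances$features)), function(i)
    global_efficiency(binarize(
      vector_to_dps(instances$features[i, ], instances$icn_names), tau)),
    numeric(1L))
}

#' State-wise condition contrast of global efficiency
#'
#' Welch t-test of per-window efficiencies between conditions within each
#' state, BH-corrected across states.
#'
#' @param efficiencies per-instance efficiency vector.
#' @param assignments integer state per instance.
#' @param labels per-instance condition labels.
#' @param conditions length-2 character; contrast is `conditions[2]` minus
#'   `conditions[1]`.
#' @param alpha significance level on the q-values.
#' @return data.frame with one row per state.
#' @export
efficiency_contrast <- function(efficiencies, assignments, labels,
                                conditions = c("EO", "EC"), alpha = 0.05) {
  out <- list()
  for (s in sort(unique(assignments))) {
    i1 <- assignments == s & labels == conditions[2L]
    i2 <- assignments == s & labels == conditions[1L]
    if (sum(i1) < 2L || sum(i2) < 2L) {
      warnf("state %d lacks >= 2 instances per condition; skipped", s)
      next
    }
    tt <- welch_t(matrix(efficiencies[i1], ncol = 1L),
                  matrix(efficiencies[i2], ncol = 1L))
    out[[length(out) + 1L]] <- data.frame(
      state = s, mean_g1 = tt$mean1, mean_g2 = tt$mean2, t = tt$t,
      p = tt$p,
      direction = ifelse(tt$mean1 >= tt$mean2,
                         paste0(conditions[2L], ">", conditions[1L]),
                         paste0(conditions[2L], "<", conditions[1L])))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!is.null(res)) {
    res$q <- stats::p.adjust(res$p, method = "BH")
    res$significant <- res$q < alpha
    names(res)[names(res) %in% c("mean_g1", "mean_g2")] <-
      paste0("mean_", conditions[c(2L, 1L)])
  }
  res
}
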