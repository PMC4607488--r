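welch_t <- function(x, y) {
  # vectorized Welch two-sample t over columns of x (group 1) and y (group 2)
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- apply(x, 2L, stats::var); v2 <- apply(y, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  d <- m1 - m2
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df), 0)
  p[t == 0] <- 1
  data.frame(mean1 = m1, mean2 = m2, t = t, df = df, p = p)
}

#' State-wise condition contrasts of synchrony and amplitude features
#'
#' Within each micro-state, every pairwise dPS feature and every
#' per-network dAMP feature is compared between the two conditions with a
#' Welch two-sample t-test; false-discovery-rate correction
#' (Benjamini-Hochberg) is applied within each state separately for the
#' synchrony family and the amplitude family. Windows are treated as
#' independent observations, as the test formulas assume; see the package
#' vignette for the autocorrelation caveat this inherits.
#'
#' @param instances an `instance_matrix`.
#' @param assignments integer state per instance.
#' @param conditions length-2 character: reference ordering
#'   `c(group2, group1)`; the reported direction and t-statistic are
#'   `conditions[2]` minus `conditions[1]` (default EC minus EO).
#' @param alpha significance level on the FDR-adjusted q-values.
#' @return data.frame with one row per (state, feature): `state`, `family`
#'   (`"dPS"`/`"dAMP"`), `feature`, group means, `t`, `p`, `q`,
#'   `direction`, `significant`.
#' @export
compare_conditions <- function(instances, assignments,
                               conditions = c("EO", "EC"), alpha = 0.001) {
  stopifnot(inherits(instances, "instance_matrix"))
  lab <- instances$meta$condition
  out <- list()
  for (s in sort(unique(assignments))) {
    in_s <- assignments == s
    i1 <- in_s & lab == conditions[2L]  # e.g. EC
    i2 <- in_s & lab == conditions[1L]  # e.g. EO
    if (sum(i1) < 2L || sum(i2) < 2L) {
      warnf("state %d lacks >= 2 instances in each condition; skipped", s)
      next
    }
    for (fam in c("dPS", "dAMP")) {
      x <- if (fam == "dPS") instances$features else instances$damp
      tt <- welch_t(x[i1, , drop = FALSE], x[i2, , drop = FALSE])
      q <- stats::p.adjust(tt$p, method = "BH")
      out[[length(out) + 1L]] <- data.frame(
        state = s, family = fam, feature = colnames(x),
        mean_g1 = tt$mean1, mean_g2 = tt$mean2,
        t = tt$t, p = tt$p, q = q,
        direction = ifelse(tt$mean1 >= tt$mean2,
                           paste0(conditions[2L], ">", conditions[1L]),
                           paste0(conditions[2L], "<", conditions[1L])),
        significant = q < alpha)
    }
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  names(res)[names(res) == "mean_g1"] <- paste0("mean_", conditions[2L])
  names(res)[names(res) == "mean_g2"] <- paste0("mean_", conditions[1L])
  res
}

#' Fisher r-to-z transform
#'
#' The variance-stabilizing transform `z = (ln(1+r) - ln(1-r))/2 =
#' atanh(r)` of a Pearson correlation.
#'
#' @param r correlation(s), `|r| < 1`.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stopf("|r| must be < 1 for the Fisher transform")
  atanh(r)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` with `z_i = atanh(r_i)`;
#' the p-value is the two-sided standard-normal tail probability.
#'
#' @param r1,r2 Pearson correlations of the two groups, `|r| < 1`.
#' @param n1,n2 group sizes, each `> 3`.
#' @return list of class `correlation_comparison`: `r1`, `r2`, `n1`, `n2`,
#'   `z1`, `z2`, `z`, `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stopf("both group sizes must exceed 3")
  z1 <- fisher_z(r1); z2 <- fisher_z(r2)
  z <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(r1 = r1, r2 = r2, n1 = n1, n2 = n2, z1 = z1, z2 = z2,
                 z = z, p = 2 * stats::pnorm(-abs(z))),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("r1 = %.3f (n = %d) vs r2 = %.3f (n = %d): z = %.3f, p = %.4g\n",
              x$r1, x$n1, x$r2, x$n2, x$z, x$p))
  invisible(x)
}

#' Per-instance node strength of one network
#'
#' Mean synchrony of the chosen network to the other K-1 networks within
#' each window.
#'
#' @param instances an `instance_matrix`.
#' @param icn network name or index.
#' @return numeric vector, one value per instance.
#' @export
icn_strength <- function(instances, icn = "DMN") {
  stopifnot(inherits(instances, "instance_matrix"))
  if (is.character(icn)) icn <- match(icn, instances$icn_names)
  if (is.na(icn) || icn < 1L || icn > length(instances$icn_names))
    stopf("unknown network")
  pr <- icn_pairs(instances$icn_names)
  cols <- which(pr$i == icn | pr$j == icn)
  rowMeans(instances$features[, cols, drop = FALSE])
}

cor_with_p <- function(x, y) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), n = n)
}

#' Amplitude-strength coupling of one network, by state and condition
#'
#' Within each state and condition, the Pearson correlation between the
#' chosen network's windowed amplitude (dAMP) and its node strength (mean
#' dPS to the other networks), followed by an eyes-closed versus eyes-open
#' contrast of the two correlations via [compare_correlations()].
#'
#' @param instances an `instance_matrix`.
#' @param assignments integer state per instance.
#' @param icn network of interest (default the default mode network).
#' @param conditions length-2 character; the contrast is
#'   `conditions[2]` minus `conditions[1]`.
#' @param min_n smallest per-group size analysed (Fisher machinery needs
#'   n > 3); states with a smaller group are skipped.
#' @return list with `correlations` (state, condition, n, r, p) and
#'   `contrasts` (state, r per group, z, p).
#' @export
amplitude_strength_relationship <- function(instances, assignments,
                                            icn = "DMN",
                                            conditions = c("EO", "EC"),
                                            min_n = 4L) {
  stopifnot(inherits(instances, "instance_matrix"))
  icn_name <- if (is.character(icn)) icn else instances$icn_names[icn]
  amp <- instances$damp[, icn_name]
  strength <- icn_strength(instances, icn_name)
  lab <- instances$meta$condition
  cors <- list(); cons <- list()
  for (s in sort(unique(assignments))) {
    per_cond <- lapply(conditions, function(cc) {
      idx <- assignments == s & lab == cc
      if (sum(idx) < min_n) NULL else cor_with_p(amp[idx], strength[idx])
    })
    names(per_cond) <- conditions
    if (any(vapply(per_cond, is.null, logical(1L)))) {
      warnf("state %d has a condition with < %d instances; skipped", s, min_n)
      next
    }
    for (cc in conditions)
      cors[[length(cors) + 1L]] <- data.frame(
        state = s, condition = cc, n = per_cond[[cc]]$n,
        r = per_cond[[cc]]$r, p = per_cond[[cc]]$p)
    g1 <- per_cond[[conditions[2L]]]; g2 <- per_cond[[conditions[1L]]]
    if (!is.na(g1$r) && !is.na(g2$r)) {
      cmp <- compare_correlations(g1$r, g1$n, g2$r, g2$n)
      cons[[length(cons) + 1L]] <- data.frame(
        state = s, r_g1 = g1$r, n_g1 = g1$n, r_g2 = g2$r, n_g2 = g2$n,
        z = cmp$z, p = cmp$p)
    }
  }
  correlations <- do.call(rbind, c(cors, list(make.row.names = FALSE)))
  contrasts <- do.call(rbind, c(cons, list(make.row.names = FALSE)))
  if (!is.null(contrasts)) {
    names(contrasts)[2:5] <- c(paste0("r_", conditions[2L]),
                               paste0("n_", conditions[2L]),
                               paste0("r_", conditions[1L]),
                               paste0("n_", conditions[1L]))
  }
  list(correlations = correlations, contrasts = contrasts)
}

#' Condition contrast of amplitude-synchrony coupling across all pairs
#'
#' For every network pair, the correlation between the reference network's
#' windowed amplitude and that pair's dPS is computed within state and
#' condition; the two conditions are contrasted via
#' [compare_correlations()] and FDR-corrected (BH) across the pairs within
#' each state. Pairs whose inputs are degenerate (zero variance) in either
#' group are flagged and excluded from testing.
#'
#' @inheritParams amplitude_strength_relationship
#' @param ref_icn reference network whose amplitude drives the coupling.
#' @param alpha significance level on the q-values.
#' @return list with `table` (tidy per state x pair rows) and `maps` (per
#'   state, K x K symmetric matrices `z`, `q` and signed significance
#'   `sig`, with empty diagonal).
#' @export
amplitude_ps_contrast <- function(instances, assignments, ref_icn = "DMN",
                                  conditions = c("EO", "EC"),
                                  alpha = 0.001, min_n = 4L) {
  stopifnot(inherits(instances, "instance_matrix"))
  ref_name <- if (is.character(ref_icn)) ref_icn else
    instances$icn_names[ref_icn]
  amp <- instances$damp[, ref_name]
  lab <- instances$meta$condition
  pr <- icn_pairs(instances$icn_names)
  k <- length(instances$icn_names)
  rows <- list(); maps <- list()
  for (s in sort(unique(assignments))) {
    i1 <- assignments == s & lab == conditions[2L]
    i2 <- assignments == s & lab == conditions[1L]
    if (sum(i1) < min_n || sum(i2) < min_n) {
      warnf("state %d has a condition with < %d instances; skipped", s, min_n)
      next
    }
    res <- lapply(seq_len(nrow(pr)), function(pp) {
      c1 <- cor_with_p(amp[i1], instances$features[i1, pp])
      c2 <- cor_with_p(amp[i2], instances$features[i2, pp])
      if (is.na(c1$r) || is.na(c2$r) || abs(c1$r) >= 1 || abs(c2$r) >= 1)
        return(data.frame(r_g1 = c1$r, r_g2 = c2$r, z = NA_real_,
                          p = NA_real_, degenerate = TRUE))
      cmp <- compare_correlations(c1$r, c1$n, c2$r, c2$n)
      data.frame(r_g1 = c1$r, r_g2 = c2$r, z = cmp$z, p = cmp$p,
                 degenerate = FALSE)
    })
    res <- do.call(rbind, res)
    q <- rep(NA_real_, nrow(res))
    q[!res$degenerate] <- stats::p.adjust(res$p[!res$degenerate],
                                          method = "BH")
    zmat <- qmat <- matrix(NA_real_, k, k,
                           dimnames = list(instances$icn_names,
                                           instances$icn_names))
    zmat[cbind(pr$i, pr$j)] <- zmat[cbind(pr$j, pr$i)] <- res$z
    qmat[cbind(pr$i, pr$j)] <- qmat[cbind(pr$j, pr$i)] <- q
    sig <- ifelse(!is.na(qmat) & qmat < alpha, sign(zmat), 0)
    diag(sig) <- 0
    maps[[paste0("state", s)]] <- list(z = zmat, q = qmat, sig = sig)
    rows[[length(rows) + 1L]] <- data.frame(
      state = s, pair = pr$name, r_g1 = res$r_g1, r_g2 = res$r_g2,
      z = res$z, p = res$p, q = q, degenerate = res$degenerate)
  }
  table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(table))
    names(table)[names(table) %in% c("r_g1", "r_g2")] <-
      paste0("r_", conditions[c(2L, 1L)])
  list(table = table, maps = maps)
}
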