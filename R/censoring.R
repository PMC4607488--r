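#' Framewise displacement from rigid-body motion parameters
#'
#' Sum of absolute backward differences of the six realignment parameters,
#' with the three rotations converted to arc length on a sphere of
#' `head_radius` mm. The first sample has no predecessor and is set to 0.
#'
#' @param motion T x 6 matrix (or 6 x T, transposed automatically): three
#'   translations in mm then three rotations in radians.
#' @param head_radius sphere radius in mm for the rotation conversion.
#' @return numeric FD series in mm, length T.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) == 6L && ncol(motion) != 6L) motion <- t(motion)
  if (ncol(motion) != 6L)
    stopf("motion must have 6 parameters, got %d", ncol(motion))
  p <- motion
  p[, 4:6] <- p[, 4:6] * head_radius
  c(0, rowSums(abs(diff(p))))
}

#' Normalized DVARS of a volume series
#'
#' Root-mean-square across voxels of the temporal backward difference,
#' divided by its median so artifact-free data sit near 1. The first
#' sample, which has no predecessor, is assigned the median value 1.
#' A series constant in time is degenerate (all-zero raw DVARS): the
#' all-zero series is returned with attribute `degenerate = TRUE` and flags
#' no outliers downstream.
#'
#' @param volumes voxels x time matrix.
#' @return normalized DVARS series of length `ncol(volumes)`.
#' @export
dvars <- function(volumes) {
  volumes <- as.matrix(volumes)
  if (ncol(volumes) < 2L) stopf("DVARS needs at least 2 time points")
  d <- diff(t(volumes))
  raw <- sqrt(rowMeans(d^2))
  med <- stats::median(raw)
  if (med <= 0)
    return(structure(rep(0, ncol(volumes)), degenerate = TRUE))
  c(1, raw / med)
}

#' Boxplot outlier mask
#'
#' Flags values outside 1.5 times the interquartile range beyond the
#' quartiles, with quartiles computed by the linear-interpolation
#' convention (`stats::quantile` type 7).
#'
#' @param x numeric series, length >= 4.
#' @return logical mask of the same length.
#' @export
boxplot_outliers <- function(x) {
  if (length(x) < 4L) stopf("boxplot outliers need at least 4 values")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  x < q[1L] - 1.5 * iqr | x > q[2L] + 1.5 * iqr
}

#' Mark motion-corrupted samples
#'
#' Base marks where FD exceeds `fd_thresh` or DVARS is a boxplot outlier of
#' the whole series; marks are then dilated by one sample on each side
#' (clipped at the series ends), since the volumes neighbouring an
#' artifactual time point are suspect too.
#'
#' @param fd FD series in mm.
#' @param dvars normalized DVARS series (optional; `NULL` to censor on FD
#'   alone, e.g. when no volumetric data exist). A series flagged degenerate
#'   by [dvars()] contributes no marks.
#' @param fd_thresh FD threshold in mm.
#' @return logical series of final marks.
#' @export
mark_artifacts <- function(fd, dvars = NULL, fd_thresh = 0.5) {
  base <- fd > fd_thresh
  if (!is.null(dvars)) {
    if (length(dvars) != length(fd))
      stopf("fd and dvars have different lengths (%d vs %d)",
            length(fd), length(dvars))
    if (!isTRUE(attr(dvars, "degenerate")))
      base <- base | boxplot_outliers(as.numeric(dvars))
  }
  n <- length(base)
  base | c(base[-1L], FALSE) | c(FALSE, base[-n])
}

#' Retain only artifact-free windows
#'
#' A window survives censoring iff none of its `m + 1` samples is marked.
#'
#' @param windows window table from [sliding_windows()].
#' @param marked logical per-sample artifact series.
#' @return integer vector of retained window indices (possibly empty).
#' @export
censor_windows <- function(windows, marked) {
  if (max(windows$end) > length(marked))
    stopf("windows exceed mark series length")
  hits <- window_sums(as.numeric(marked), windows)
  windows$index[hits == 0]
}

#' Per-session censoring summary
#'
#' Convenience wrapper: FD from the motion parameters, artifact marks
#' (optionally combined with DVARS), and the retained window set.
#'
#' @param motion T x 6 motion-parameter matrix.
#' @param windows window table matching the session's feature windows.
#' @param dvars optional normalized DVARS series.
#' @param fd_thresh FD threshold in mm.
#' @param head_radius rotation-to-arc-length radius in mm.
#' @return object of class `censor_mask`: list with `fd`, `marked`,
#'   `retained_windows`.
#' @export
censor_session <- function(motion, windows, dvars = NULL, fd_thresh = 0.5,
                           head_radius = 50) {
  fd <- framewise_displacement(motion, head_radius = head_radius)
  marked <- mark_artifacts(fd, dvars = dvars, fd_thresh = fd_thresh)
  structure(list(fd = fd, marked = marked,
                 retained_windows = censor_windows(windows, marked)),
            class = "censor_mask")
}
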