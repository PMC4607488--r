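#' ICN time courses by spatial regression (dual-regression stage 1)
#'
#' At each time point the volume (a vector over voxels) is regressed onto
#' the K spatial template maps plus an intercept by ordinary least squares;
#' the K beta series form the network time courses. Templates are z-scored
#' across voxels beforehand (the dual-regression convention), and the
#' intercept absorbs the global mean so it does not leak into the betas.
#'
#' @param volumes numeric voxels x time matrix (flattened 4D series).
#' @param templates numeric voxels x K matrix of spatial maps; column names
#'   are taken as network labels (default [default_icn_names()]).
#' @param tr sampling interval in seconds, attached to the result.
#' @param subject,condition session metadata.
#' @return a [time_course_set()] of K beta series.
#' @export
spatial_glm_timecourses <- function(volumes, templates, tr = 2,
                                    subject = NA_character_,
                                    condition = NA_character_) {
  volumes <- as.matrix(volumes)
  templates <- as.matrix(templates)
  if (any(!is.finite(volumes)) || any(!is.finite(templates)))
    stopf("volumes and templates must be finite")
  if (nrow(volumes) != nrow(templates))
    stopf("voxel mismatch: volumes have %d voxels, templates %d",
          nrow(volumes), nrow(templates))
  if (ncol(volumes) < 2L) stopf("need at least 2 time points")
  k <- ncol(templates)
  if (k < 2L) stopf("need at least 2 template maps")
  icn <- colnames(templates) %||% default_icn_names(k)
  zmaps <- scale(templates)
  design <- cbind(intercept = 1, zmaps)
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    dropped <- colnames(design)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(design))]]
    stopf("rank-deficient spatial design; collinear template(s): %s",
          paste(dropped, collapse = ", "))
  }
  betas <- qr.coef(qrx, volumes)[-1L, , drop = FALSE]
  rownames(betas) <- icn
  time_course_set(betas, tr = tr, subject = subject, condition = condition)
}

#' Zero-phase temporal band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, the standard
#' 0.01-0.08 Hz resting-state band by default. Zero-phase filtering matters
#' here because downstream instantaneous-phase estimates must not inherit a
#' filter phase lag. DC is removed by construction.
#'
#' @param x real numeric series.
#' @param fs sampling frequency in Hz (1/TR).
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return filtered series, same length as `x`.
#' @export
bandpass <- function(x, fs, low = 0.01, high = 0.08, order = 2L) {
  if (!(low > 0 && low < high && high < fs / 2))
    stopf("infeasible band [%g, %g] Hz at fs = %g Hz (need 0 < low < high < fs/2)",
          low, high, fs)
  if (length(x) < 3 * fs / low)
    stopf("series too short for the band: need >= 3 periods of the slowest component (%d samples)",
          ceiling(3 * fs / low))
  filt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # demean first: the filter has zero DC gain in steady state, but a large
  # offset would otherwise leak into the forward-backward edge transients
  as.numeric(signal::filtfilt(filt, x - mean(x)))
}

#' Read a 4D NIfTI series as a voxels x time matrix
#'
#' Convenience reader for volumetric input (requires the RNifti package).
#' Voxels with zero temporal variance are dropped; the retained voxel mask
#' is attached as attribute `mask` so template maps can be subset
#' identically via [mask_template_maps()].
#'
#' @param path NIfTI file (3D series of K maps or 4D functional).
#' @return numeric matrix, voxels x time, with attribute `mask`.
#' @export
read_nifti_volumes <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stopf("reading NIfTI requires the RNifti package")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stopf("expected a 4D NIfTI image, got %dD", length(d))
  mat <- matrix(as.numeric(img), prod(d[1:3]), d[4L])
  v <- apply(mat, 1L, stats::var)
  mask <- is.finite(v) & v > 0
  structure(mat[mask, , drop = FALSE], mask = mask)
}

#' @rdname read_nifti_volumes
#' @param maps voxels x K template matrix covering the full grid.
#' @param mask logical mask as attached by `read_nifti_volumes`.
#' @export
mask_template_maps <- function(maps, mask) {
  as.matrix(maps)[mask, , drop = FALSE]
}
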