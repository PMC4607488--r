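#' Analytic signal via the Hilbert transform
#'
#' Computes the discrete analytic signal `s(t) + i * H[s](t)` of a real
#' series using the frequency-domain Hilbert multiplier (-i for positive
#' frequencies, +i for negative, 0 at DC and Nyquist). The instantaneous
#' amplitude is the modulus and the instantaneous phase the argument of the
#' analytic signal, in (-pi, pi].
#'
#' @param x real numeric series, length >= 8, finite, non-constant.
#' @return list with components `phase` and `amplitude`, each of length
#'   `length(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 8L) stopf("analytic_signal needs at least 8 samples, got %d", n)
  if (!is.numeric(x) || any(!is.finite(x))) stopf("series must be finite numeric")
  if (stats::var(x) == 0) stopf("constant series: instantaneous phase undefined")
  X <- stats::fft(x)
  H <- complex(real = rep(0, n), imaginary = rep(0, n))
  if (n %% 2L == 0L) {
    pos <- seq(2L, n / 2L)
    neg <- seq(n / 2L + 2L, n)
  } else {
    pos <- seq(2L, (n + 1L) / 2L)
    neg <- seq((n + 3L) / 2L, n)
  }
  H[pos] <- complex(imaginary = -1)
  H[neg] <- complex(imaginary = 1)
  xh <- Re(stats::fft(X * H, inverse = TRUE)) / n
  z <- complex(real = x, imaginary = xh)
  list(phase = Arg(z), amplitude = Mod(z))
}

#' Sliding-window bookkeeping
#'
#' A window with parameter `m` starting at sample `i` spans samples
#' `i..i+m` inclusive, i.e. `m + 1` samples — the summation limits of the
#' windowed synchrony and amplitude statistics. With unit step a series of
#' `T` samples yields `T - m` windows (235 samples and m = 22 give 213).
#'
#' @param n_samples series length T.
#' @param m window length parameter in samples (span is `m + 1` samples).
#' @param step window start increment in samples.
#' @return data.frame with columns `index`, `start`, `end`.
#' @export
sliding_windows <- function(n_samples, m = 22L, step = 1L) {
  if (!is_count(n_samples) || !is_count(m) || !is_count(step))
    stopf("n_samples, m and step must be positive integers")
  if (n_samples <= m)
    stopf("need more than m = %d samples for one window (a window spans m + 1 samples); got %d",
          m, n_samples)
  starts <- seq.int(1L, n_samples - m, by = step)
  data.frame(index = seq_along(starts), start = starts, end = starts + m)
}

window_sums <- function(v, windows) {
  cs <- c(0, cumsum(v))
  cs[windows$end + 1L] - cs[windows$start]
}

#' Windowed mean phase coherence (dPS)
#'
#' For each window the resultant length of the instantaneous phase
#' differences `phi1(t) - phi2(t)` over its `m + 1` samples:
#' `sqrt(mean(cos)^2 + mean(sin)^2)`, a value in [0, 1] (1 = perfect
#' locking, ~0 = uniform scatter). Wrap-invariant by construction.
#'
#' @param phi1,phi2 phase series in radians, equal length.
#' @param windows window table from [sliding_windows()].
#' @return numeric vector, one dPS value per window.
#' @export
dynamic_phase_synchrony <- function(phi1, phi2, windows) {
  if (length(phi1) != length(phi2))
    stopf("phase series have different lengths (%d vs %d)",
          length(phi1), length(phi2))
  if (max(windows$end) > length(phi1))
    stopf("windows exceed series length")
  d <- phi1 - phi2
  span <- windows$end - windows$start + 1L
  mc <- window_sums(cos(d), windows) / span
  ms <- window_sums(sin(d), windows) / span
  pmin(sqrt(mc^2 + ms^2), 1)
}

#' Windowed mean instantaneous amplitude (dAMP)
#'
#' Mean of the instantaneous amplitude over each window's `m + 1` samples.
#'
#' @param amplitude non-negative amplitude series.
#' @param windows window table from [sliding_windows()].
#' @return numeric vector, one dAMP value per window.
#' @export
dynamic_amplitude <- function(amplitude, windows) {
  if (any(amplitude < 0)) stopf("amplitudes must be non-negative")
  if (max(windows$end) > length(amplitude))
    stopf("windows exceed series length")
  window_sums(amplitude, windows) / (windows$end - windows$start + 1L)
}

#' Network-pair labels for the vectorized upper triangle
#'
#' Row-major upper-triangle ordering: (1,2), (1,3), ..., (1,K), (2,3), ...
#'
#' @param icn_names K network labels.
#' @return data.frame with columns `i`, `j`, `name` of length K(K-1)/2.
#' @export
icn_pairs <- function(icn_names) {
  k <- length(icn_names)
  idx <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(i = idx[, 1L], j = idx[, 2L],
             name = paste(icn_names[idx[, 1L]], icn_names[idx[, 2L]],
                          sep = "-"))
}

#' Rebuild a symmetric synchrony matrix from its vectorized upper triangle
#'
#' Inverse of the row-major upper-triangle vectorization used throughout;
#' the diagonal is set to 1 (self-synchrony).
#'
#' @param v numeric vector of length K(K-1)/2.
#' @param icn_names K network labels.
#' @return K x K symmetric matrix with unit diagonal.
#' @export
vector_to_dps <- function(v, icn_names) {
  k <- length(icn_names)
  pr <- icn_pairs(icn_names)
  m <- diag(1, k)
  m[cbind(pr$i, pr$j)] <- v
  m[cbind(pr$j, pr$i)] <- v
  dimnames(m) <- list(icn_names, icn_names)
  m
}

#' Sliding-window synchrony and amplitude features of a session
#'
#' Computes the analytic signal of every network time course (on the full
#' series, before any windowing, so the low-frequency phase estimates are
#' undistorted), then all K(K-1)/2 pairwise dPS series and K dAMP series on
#' a shared window set.
#'
#' @param tcs a [time_course_set()].
#' @param m window length parameter in samples.
#' @param step window step in samples.
#' @return object of class `windowed_features`: list with `dps` (n x P
#'   matrix, P = K(K-1)/2, columns named by pair), `damp` (n x K matrix),
#'   `windows`, `icn_names`, `pairs`, and the session metadata.
#' @export
windowed_features <- function(tcs, m = 22L, step = 1L) {
  stopifnot(inherits(tcs, "time_course_set"))
  k <- nrow(tcs$data)
  if (k < 2L) stopf("need at least 2 networks for pairwise synchrony")
  windows <- sliding_windows(ncol(tcs$data), m = m, step = step)
  icn <- rownames(tcs$data)
  an <- lapply(seq_len(k), function(i) analytic_signal(tcs$data[i, ]))
  phase <- vapply(an, `[[`, numeric(ncol(tcs$data)), "phase")
  amp <- vapply(an, `[[`, numeric(ncol(tcs$data)), "amplitude")
  pr <- icn_pairs(icn)
  dps <- mapply(function(i, j)
    dynamic_phase_synchrony(phase[, i], phase[, j], windows),
    pr$i, pr$j)
  dps <- matrix(dps, nrow = nrow(windows), dimnames = list(NULL, pr$name))
  damp <- apply(amp, 2L, dynamic_amplitude, windows = windows)
  damp <- matrix(damp, nrow = nrow(windows), dimnames = list(NULL, icn))
  structure(list(dps = dps, damp = damp, windows = windows,
                 icn_names = icn, pairs = pr, m = m, step = step,
                 tr = tcs$tr, subject = tcs$subject,
                 condition = tcs$condition),
            class = "windowed_features")
}

#' Extract one window's synchrony matrix
#'
#' @param feats a [windowed_features()] object.
#' @param w window index.
#' @return K x K symmetric dPS matrix with unit diagonal.
#' @export
dps_matrix <- function(feats, w) {
  stopifnot(inherits(feats, "windowed_features"))
  vector_to_dps(feats$dps[w, ], feats$icn_names)
}

#' @export
print.windowed_features <- function(x, ...) {
  cat(sprintf(
    "windowed_features: %d windows (m = %d, step = %d), %d pairs + %d amplitudes\n",
    nrow(x$windows), x$m, x$step, ncol(x$dps), ncol(x$damp)))
  invisible(x)
}

#' Write per-session windowed features as tab-separated text
#'
#' One row per window: window index, the named pairwise dPS columns, then
#' the named per-network dAMP columns.
#'
#' @param feats a [windowed_features()] object.
#' @param path output file.
#' @export
write_features <- function(feats, path) {
  df <- data.frame(window = feats$windows$index, feats$dps,
                   feats$damp, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
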