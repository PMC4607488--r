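# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a single finite number")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

#' Default ICN labels
#'
#' The ten intrinsic connectivity networks analysed throughout the package,
#' in their conventional order: medial, occipital and lateral visual networks,
#' default mode network, cerebellum, sensorimotor and auditory networks,
#' executive control network, and right/left frontoparietal networks.
#' For other values of `k` generic labels are produced.
#'
#' @param k number of networks.
#' @return character vector of length `k`.
#' @export
default_icn_names <- function(k = 10L) {
  if (k == 10L)
    c("MVN", "OVN", "LVN", "DMN", "CBN", "SMN", "AN", "ECN", "RFPN", "LFPN")
  else
    paste0("ICN", seq_len(k))
}
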