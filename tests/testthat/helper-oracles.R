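# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# scalar-loop mean phase coherence over one window
oracle_dps <- function(phi1, phi2, start, end) {
  sc <- ss <- 0
  for (t in start:end) {
    d <- phi1[t] - phi2[t]
    sc <- sc + cos(d)
    ss <- ss + sin(d)
  }
  n <- end - start + 1
  sqrt((sc / n)^2 + (ss / n)^2)
}

# scalar-loop windowed mean amplitude
oracle_damp <- function(a, start, end) {
  s <- 0
  for (t in start:end) s <- s + a[t]
  s / (end - start + 1)
}

# analytic signal by explicit half-spectrum construction (zero the negative
# frequencies, double the positive ones, keep DC and Nyquist)
oracle_analytic <- function(x) {
  n <- length(x)
  z <- fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(z * h, inverse = TRUE) / n
}

# step-by-step Ward agglomeration on squared Euclidean distances
# (variance-minimizing Lance-Williams update); returns the merge history as
# a list of the two sets of original indices joined at each step
oracle_ward_merges <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  clusters <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  active <- seq_len(n)
  merges <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); best_val <- Inf
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1L)) {
      a <- active[ii]; b <- active[jj]
      if (d2[a, b] < best_val) {
        best_val <- d2[a, b]; best <- c(b, a)  # lowest pair first
      }
    }
    a <- best[1]; b <- best[2]
    merges[[length(merges) + 1]] <- list(sort(clusters[[a]]),
                                         sort(clusters[[b]]))
    # Lance-Williams update for Ward (on squared distances)
    for (k in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nk <- sizes[k]
      d2[a, k] <- d2[k, a] <-
        ((na + nk) * d2[a, k] + (nb + nk) * d2[b, k] - nk * d2[a, b]) /
        (na + nb + nk)
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  merges
}

# translate an hclust merge table into the same set-pair representation
hclust_merges <- function(tree) {
  members <- list()
  out <- list()
  for (s in seq_len(nrow(tree$merge))) {
    get_set <- function(v) if (v < 0) -v else members[[v]]
    a <- get_set(tree$merge[s, 1]); b <- get_set(tree$merge[s, 2])
    out[[s]] <- list(sort(a), sort(b))
    members[[s]] <- c(a, b)
  }
  out
}

# unordered comparison of one merge step
same_merge <- function(m1, m2) {
  (identical(m1[[1]], m2[[1]]) && identical(m1[[2]], m2[[2]])) ||
    (identical(m1[[1]], m2[[2]]) && identical(m1[[2]], m2[[1]]))
}

# all-pairs shortest paths by Floyd-Warshall; efficiency as mean 1/d
oracle_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# quartile fence outliers computed from first principles (type-7 quantiles)
oracle_box_outliers <- function(x) {
  s <- sort(x)
  n <- length(x)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75); iqr <- q3 - q1
  x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr
}

# windows retained iff no marked sample, by direct enumeration
oracle_retained <- function(windows, marked) {
  keep <- logical(nrow(windows))
  for (i in seq_len(nrow(windows)))
    keep[i] <- !any(marked[windows$start[i]:windows$end[i]])
  windows$index[keep]
}

# small cohort used across tests: quick to generate, still multi-state
tiny_spec <- function(seed = 7, ...) {
  defaults <- list(n_subjects = 3L, n_volumes = 120L, dwell_min = 40L,
                   n_states = 2L,
                   state_partitions = default_state_partitions(2, 10),
                   amplitude_profiles = default_amplitude_profiles(2, 10),
                   seed = seed)
  ov <- list(...)
  args <- defaults
  args[names(ov)] <- ov   # plain replacement (modifyList merges sublists)
  do.call(synthetic_spec, args)
}

null_condition_effects <- function(n_icns = 10L)
  list(EO = list(amplitude = rep(1, n_icns), coupling = rep(1, n_icns)),
       EC = list(amplitude = rep(1, n_icns), coupling = rep(1, n_icns)))

# per-session ground-truth state of each window (majority vote)
truth_window_states <- function(session, n_samples, m, step) {
  w <- sliding_windows(n_samples, m, step)
  vapply(seq_len(nrow(w)), function(i) {
    s <- session$truth$state_sequence[w$start[i]:w$end[i]]
    as.integer(names(which.max(table(s))))
  }, integer(1))
}
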