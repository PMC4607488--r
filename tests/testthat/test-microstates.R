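make_features <- function(n, seed, subject = "s1", condition = "EO",
                          n_samples = n + 22) {
  set.seed(seed)
  x <- matrix(cumsum(rnorm(10 * n_samples)), 10, n_samples)
  windowed_features(time_course_set(x, subject = subject,
                                    condition = condition), m = 22)
}

test_that("concatenation stacks retained windows with aligned metadata", {
  f1 <- make_features(213, 71, "s1", "EO")
  f2 <- make_features(213, 72, "s1", "EC")
  inst <- concatenate_features(list(f1, f2))
  expect_equal(nrow(inst$features), 426)
  expect_equal(nrow(inst$damp), 426)
  expect_equal(table(inst$meta$condition)[["EO"]], 213)
  # round-trip: row r refolds to the session's window matrix
  expect_equal(vector_to_dps(inst$features[300, ], inst$icn_names),
               dps_matrix(f2, inst$meta$window[300]))
  # censoring subset respected
  expect_warning(
    inst2 <- concatenate_features(list(f1, f2), list(1:50, integer(0))),
    "no retained windows")
  expect_equal(nrow(inst2$features), 50)
  expect_equal(unique(inst2$meta$condition), "EO")
})

test_that("concatenation rejects sessions with different networks", {
  f1 <- make_features(50, 73)
  f2 <- make_features(50, 74)
  f2$icn_names[1] <- "XXX"
  expect_error(concatenate_features(list(f1, f2)), "disagree")
})

test_that("cluster-number detection finds well-separated planted Gaussians", {
  set.seed(75)
  centers <- rbind(c(10, 0, 0, 0, 0, 0),
                   c(0, 10, 0, 0, 0, 0),
                   c(0, 0, 10, 0, 0, 0))
  x <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(rnorm(80 * 6), 80, 6), 2, centers[g, ], "+")))
  det <- detect_cluster_number(x, draw_size = 120, n_sims = 20, seed = 76)
  expect_equal(det$k, 3L)
  expect_gte(det$histogram[["3"]], 18)        # >= 90 percent of draws
  # determinism under a fixed seed
  det2 <- detect_cluster_number(x, draw_size = 120, n_sims = 20, seed = 76)
  expect_identical(det$histogram, det2$histogram)
})

test_that("a single spherical Gaussian yields modal k = 1", {
  set.seed(77)
  x <- matrix(rnorm(300 * 4), 300, 4)
  det <- detect_cluster_number(x, draw_size = 150, n_sims = 10, seed = 78)
  expect_equal(det$k, 1L)
})

test_that("degenerate zero-variance features are rejected", {
  x <- cbind(rnorm(50), rep(1, 50))
  expect_error(detect_cluster_number(x, n_sims = 2, seed = 1), "zero variance")
})

test_that("Ward merge sequence equals the brute-force agglomeration oracle", {
  for (seed in 81:84) {
    set.seed(seed)
    x <- matrix(rnorm(12 * 5), 12, 5)
    tree <- hierarchical_cluster(x, 1)$tree
    got <- hclust_merges(tree)
    want <- oracle_ward_merges(x)
    expect_length(got, 11)
    for (s in seq_along(want))
      expect_true(same_merge(got[[s]], want[[s]]),
                  label = sprintf("merge step %d, seed %d", s, seed))
  }
})

test_that("clearly separated blobs are recovered and boundaries validated", {
  set.seed(85)
  x <- rbind(matrix(rnorm(40 * 3), 40, 3),
             matrix(rnorm(40 * 3, mean = 12), 40, 3))
  labels <- rep(1:2, each = 40)
  cl <- hierarchical_cluster(x, 2)
  expect_equal(mclust::adjustedRandIndex(cl$assignments, labels), 1)
  expect_equal(sort(unique(hierarchical_cluster(x, nrow(x))$assignments)),
               1:80)
  expect_error(hierarchical_cluster(x, 81), "1..N")
})

test_that("clustering is invariant to instance order up to relabeling", {
  set.seed(86)
  x <- rbind(matrix(rnorm(30 * 4), 30, 4),
             matrix(rnorm(30 * 4, 6), 30, 4),
             matrix(rnorm(30 * 4, -6), 30, 4))
  a1 <- hierarchical_cluster(x, 3)$assignments
  perm <- sample(nrow(x))
  a2 <- hierarchical_cluster(x[perm, ], 3)$assignments
  expect_equal(mclust::adjustedRandIndex(a1[perm], a2), 1)
})

test_that("state summaries: centroids are member means, fractions sum to 100", {
  f1 <- make_features(60, 87, "s1", "EO")
  f2 <- make_features(60, 88, "s2", "EC")
  inst <- concatenate_features(list(f1, f2))
  set.seed(89)
  asg <- sample(1:3, 120, replace = TRUE)
  model <- summarize_states(inst, asg)
  expect_equal(colSums(model$fractions), c(EC = 100, EO = 100))
  for (s in 1:3) {
    expect_equal(unname(model$centroid_vectors[s, ]),
                 unname(colMeans(inst$features[asg == s, , drop = FALSE])))
    expect_equal(unname(model$amplitude_profiles[s, ]),
                 unname(colMeans(inst$damp[asg == s, , drop = FALSE])))
    expect_true(isSymmetric(model$centroids[[s]]))
  }
  # single state: fractions are 100 in both conditions
  m1 <- summarize_states(inst, rep(1, 120))
  expect_equal(as.numeric(m1$fractions), c(100, 100))
  # two-member state centroid is the elementwise mean
  asg2 <- c(1, 1, rep(2, 118))
  m2 <- summarize_states(inst, asg2)
  expect_equal(unname(m2$centroid_vectors[1, ]),
               unname(colMeans(inst$features[1:2, ])))
  expect_error(summarize_states(inst, c(rep(1, 119), 3)), "empty state")
})

test_that("centroid thresholding zeroes sub-threshold entries only", {
  icn <- default_icn_names(10)
  low <- vector_to_dps(rep(0.4, 45), icn)
  th <- threshold_centroid(low, 0.5)
  expect_equal(sum(th) - sum(diag(th)), 0)
  expect_equal(diag(th), diag(low))
  set.seed(90)
  v <- runif(45)
  cen <- vector_to_dps(v, icn)
  expect_equal(threshold_centroid(cen, 0), cen)
  th2 <- threshold_centroid(cen, 0.5)
  expect_equal(th2[upper.tri(th2)],
               ifelse(cen[upper.tri(cen)] < 0.5, 0, cen[upper.tri(cen)]))
  expect_error(threshold_centroid(cen, 1.2), "\\[0, 1\\]")
})

test_that("state matching recovers identity and permutations", {
  f <- make_features(100, 91)
  inst <- concatenate_features(list(f))
  set.seed(92)
  asg <- sample(1:4, 100, replace = TRUE)
  model <- summarize_states(inst, asg)
  self <- match_states(model, model)
  expect_equal(self$pairs$state_b, self$pairs$state_a)
  expect_equal(self$pairs$r, rep(1, 4), tolerance = 1e-12)
  # permuted copy: inverse permutation recovered
  perm <- c(3, 1, 4, 2)
  permuted <- model
  permuted$centroid_vectors <- model$centroid_vectors[perm, ]
  mt <- match_states(model, permuted)
  expect_equal(mt$pairs$state_b, order(perm))
  expect_equal(mt$pairs$r, rep(1, 4), tolerance = 1e-12)
})

test_that("matching independent-noise models scores below self-matching", {
  f1 <- make_features(120, 93)
  f2 <- make_features(120, 94)
  i1 <- concatenate_features(list(f1))
  i2 <- concatenate_features(list(f2))
  set.seed(95)
  m1 <- summarize_states(i1, sample(1:3, 120, replace = TRUE))
  m2 <- summarize_states(i2, sample(1:3, 120, replace = TRUE))
  cross <- match_states(m1, m2)
  expect_lt(mean(cross$pairs$r), 1)
  # unequal state counts: pair the smaller count, report the rest
  m4 <- summarize_states(i1, sample(1:4, 120, replace = TRUE))
  mt <- match_states(m4, m2)
  expect_equal(nrow(mt$pairs), 3)
  expect_length(mt$unmatched, 1)
})
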