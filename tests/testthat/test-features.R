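test_that("PCA projects onto 3 components and reports variance coverage", {
  pool <- small_pool(100, seed = 1)
  fs <- pca_features(pool, label = "Epca")
  expect_equal(ncol(fs$matrix), 3)
  expect_true(fs$metadata$variance_fraction > 0 &&
                fs$metadata$variance_fraction <= 1)

  # rows confined to an exact 3-dim affine subspace -> coverage 1
  set.seed(2)
  basis <- matrix(rnorm(64 * 3), 3, 64)
  coords <- matrix(rnorm(50 * 3), 50, 3)
  x <- coords %*% basis + rep(1, 50) %o% rnorm(64)
  p3 <- waveform_pool(x, rep(1L, 50), check_peak = FALSE)
  expect_equal(pca_features(p3)$metadata$variance_fraction, 1,
               tolerance = 1e-9)
})

test_that("component-1 projection variance equals the top covariance eigenvalue", {
  pool <- small_pool(120, seed = 2)
  fs <- pca_features(pool)
  ev <- eigen(stats::cov(pool$waveforms), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(stats::var(fs$matrix[, 1]), ev[1], tolerance = 1e-9)
})

test_that("rank-deficient pools are rejected with the achieved rank", {
  x <- outer(rnorm(20), rnorm(64)) # rank 1
  pool <- waveform_pool(x, rep(1L, 20), check_peak = FALSE)
  expect_error(pca_features(pool), "non-degenerate variance directions")
})

test_that("PCA projections are row-permutation invariant up to sign", {
  pool <- small_pool(80, seed = 3)
  perm <- sample(80)
  f1 <- pca_features(pool)$matrix
  shuffled <- waveform_pool(pool$waveforms[perm, ], pool$gt_labels[perm],
                            check_peak = FALSE)
  f2 <- pca_features(shuffled)$matrix
  for (j in 1:3)
    expect_true(isTRUE(all.equal(f2[, j], f1[perm, j])) ||
                  isTRUE(all.equal(f2[, j], -f1[perm, j])))
})

test_that("the Haar DWT is orthonormal and matches the hand pyramid", {
  # constant signal: all details zero, energy in the approximation
  cw <- haar_dwt(rep(3, 64))
  expect_equal(cw[3:64], numeric(62))
  expect_equal(sum(cw^2), sum(rep(3, 64)^2))

  # hand-computed length-8 pyramid at 3 levels
  expect_equal(haar_dwt(c(1, 1, 1, 1, 0, 0, 0, 0), levels = 3),
               c(sqrt(2), sqrt(2), 0, 0, 0, 0, 0, 0))

  # energy conservation on arbitrary input
  set.seed(4)
  x <- rnorm(64)
  expect_equal(sum(haar_dwt(x)^2), sum(x^2), tolerance = 1e-9)

  expect_error(haar_dwt(rnorm(60)), "not divisible")
})

test_that("the Haar DWT is linear", {
  set.seed(5)
  x <- rnorm(64); y <- rnorm(64)
  expect_equal(haar_dwt(2.5 * x - 1.3 * y),
               2.5 * haar_dwt(x) - 1.3 * haar_dwt(y), tolerance = 1e-9)
})

test_that("the normality deviation statistic behaves like Lilliefors' D", {
  set.seed(6)
  z <- rnorm(5000)
  expect_lt(ks_normality_deviation(z), 0.03)

  # two-point sample: closed-form empirical CDF against Phi
  v <- rep(c(-2, 2), 40)
  z2 <- sort((v - mean(v)) / sd(v))
  n <- length(z2)
  d_direct <- max(seq_len(n) / n - pnorm(z2), pnorm(z2) - (seq_len(n) - 1) / n)
  expect_equal(ks_normality_deviation(v), d_direct)

  # agrees with the established Lilliefors implementation
  expect_equal(ks_normality_deviation(z),
               unname(nortest::lillie.test(z)$statistic), tolerance = 1e-12)

  # bimodal mixtures deviate more than a same-size normal sample
  bim <- c(rnorm(500, -4), rnorm(500, 4))
  expect_gt(ks_normality_deviation(bim), ks_normality_deviation(rnorm(1000)))

  expect_warning(d0 <- ks_normality_deviation(rep(1, 20)), "zero-variance")
  expect_equal(d0, 0)
})

test_that("wavelet features keep the 10 most non-normal coefficients", {
  pool <- small_pool(100, seed = 7)
  fs <- wavelet_features(pool, label = "Eks")
  expect_equal(ncol(fs$matrix), 10)
  expect_length(fs$metadata$selected_indices, 10)

  # a single engineered bimodal coefficient must rank first
  H <- sapply(1:64, function(j) haar_dwt(replace(numeric(64), j, 1)))
  set.seed(8)
  coeffs <- matrix(rnorm(200 * 64, sd = 0.1), 200, 64)
  coeffs[, 7] <- rep(c(-5, 5), 100) + rnorm(200, sd = 0.1)
  waves <- coeffs %*% H # inverse transform (H is orthogonal)
  pool2 <- waveform_pool(waves, rep(1:2, 100), check_peak = FALSE)
  fs2 <- wavelet_features(pool2)
  expect_identical(fs2$metadata$selected_indices[1], 7L)
})

test_that("coefficient selection is row-permutation invariant", {
  pool <- small_pool(90, seed = 9)
  perm <- sample(90)
  shuffled <- waveform_pool(pool$waveforms[perm, ], pool$gt_labels[perm],
                            check_peak = FALSE)
  expect_identical(wavelet_features(pool)$metadata$selected_indices,
                   wavelet_features(shuffled)$metadata$selected_indices)
})

test_that("a degenerate single-class zero-noise pool falls back gracefully", {
  pool <- simulate_waveform_pool(sim_config(2, 20, noise_sd = 0, seed = 1))
  one <- waveform_pool(pool$waveforms[pool$gt_labels == 1, , drop = FALSE],
                       rep(1L, sum(pool$gt_labels == 1)))
  expect_warning(fs <- wavelet_features(one), "zero normality deviation")
  expect_identical(fs$metadata$selected_indices, 1:10)
})

test_that("the KNN graph has exact out-degree and brute-force weights", {
  # 12 collinear points: node 1's neighbors are 2..12 in distance order
  m <- matrix(0, 12, 3); m[, 1] <- 1:12
  fs <- feature_set(m, "pca", rep(1L, 12))
  g <- knn_graph(fs, K = 11)
  e1 <- g$edges[g$edges$source == 1, ]
  expect_identical(e1$target, 2:12)
  expect_equal(e1$weight, 1:11)

  pool <- small_pool(100, seed = 10)
  fs2 <- pca_features(pool)
  g2 <- knn_graph(fs2) # default K = 11
  expect_true(all(table(g2$edges$source) == 11))
  d <- as.matrix(dist(fs2$matrix))
  expect_equal(g2$edges$weight,
               d[cbind(g2$edges$source, g2$edges$target)], tolerance = 1e-12)

  expect_error(knn_graph(feature_set(m[1:5, ], "pca", rep(1L, 5)), K = 11),
               "more points than K")
})

test_that("KNN graphs export as 1-based 'source target weight' lines", {
  pool <- small_pool(30, seed = 11)
  g <- knn_graph(pca_features(pool), K = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_knn_graph(g, path)
  back <- read.table(path, col.names = c("source", "target", "weight"))
  expect_equal(back, g$edges, tolerance = 1e-12)
})
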