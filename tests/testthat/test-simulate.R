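test_that("template sets satisfy their similarity regime and geometry", {
  tp <- make_templates(3, "low", seed = 1)
  cors <- combn(3, 2, function(ij)
    template_correlation(tp[[ij[1]]]$shape, tp[[ij[2]]]$shape))
  expect_lt(max(cors), 0.7)

  tph <- make_templates(2, "high", seed = 1)
  expect_gt(template_correlation(tph[[1]]$shape, tph[[2]]$shape), 0.9)

  for (t in c(tp, tph)) {
    expect_length(t$shape, 64)
    expect_identical(which.max(t$shape), 20L)
    expect_equal(max(t$shape), 1) # unit peak before scaling
  }
})

test_that("template generation is deterministic per seed", {
  expect_identical(make_templates(4, "low", seed = 7),
                   make_templates(4, "low", seed = 7))
  expect_false(identical(make_templates(3, "low", seed = 7),
                         make_templates(3, "low", seed = 8)))
})

test_that("zero-noise recordings reproduce the templates at every event", {
  expect_error(sim_config(n_classes = 2, n_spikes = 30, min_separation = 10))
  cfg <- sim_config(n_classes = 2, n_spikes = 30, noise_sd = 0, seed = 2)
  rec <- simulate_recording(cfg)
  tp <- make_templates(2, "low", seed = 2)
  for (i in seq_along(rec$gt_times)) {
    w <- rec$samples[(rec$gt_times[i] - 19):(rec$gt_times[i] + 44)]
    expect_equal(w, tp[[rec$gt_labels[i]]]$shape)
  }
})

test_that("balanced class assignment is exact when divisible", {
  rec <- simulate_recording(sim_config(3, 3000, noise_sd = 0.05, seed = 7))
  expect_identical(as.vector(table(rec$gt_labels)), rep(1000L, 3))
  expect_true(all(diff(rec$gt_times) >= 100))
})

test_that("the recording trace is reproducible bit-for-bit per seed", {
  cfg <- sim_config(3, 200, noise_sd = 0.05, seed = 5)
  expect_identical(simulate_recording(cfg)$samples,
                   simulate_recording(cfg)$samples)
})

test_that("a too-short requested duration errors", {
  cfg <- sim_config(3, 100, noise_sd = 0, seed = 1, duration = 1000)
  expect_error(simulate_recording(cfg), "too short")
})

test_that("zero-noise pools equal their class templates row for row", {
  pool <- simulate_waveform_pool(sim_config(3, 30, noise_sd = 0, seed = 3))
  tp <- make_templates(3, "low", seed = 3)
  for (i in seq_len(30))
    expect_equal(pool$waveforms[i, ], tp[[pool$gt_labels[i]]]$shape)
})

test_that("per-class pool means converge to the templates", {
  pool <- simulate_waveform_pool(sim_config(3, 1200, noise_sd = 0.1, seed = 4))
  tp <- make_templates(3, "low", seed = 4)
  for (cl in 1:3) {
    rows <- pool$waveforms[pool$gt_labels == cl, ]
    # away from steep template slopes the class mean converges to the
    # template at the plain sampling rate; columns on steep slopes also
    # carry the peak-jitter bias of the re-alignment rule, so the
    # bias-free convergence check is split-half agreement: two independent
    # halves of the ensemble must agree within sampling error
    dev <- abs(colMeans(rows) - tp[[cl]]$shape)
    expect_lt(median(dev), 3 * 0.1 / sqrt(400))
    n_half <- nrow(rows) %/% 2
    half_gap <- abs(colMeans(rows[seq_len(n_half), ]) -
                      colMeans(rows[(n_half + 1):nrow(rows), ]))
    expect_lt(max(half_gap), 3 * sqrt(2) * 0.16 / sqrt(n_half))
  }
})

test_that("pools carry the requested number of classes and stay aligned", {
  pool <- simulate_waveform_pool(sim_config(4, 80, noise_sd = 0.1, seed = 6))
  expect_identical(sort(unique(pool$gt_labels)), 1:4)
  expect_true(all(apply(pool$waveforms, 1, which.max) == 20))
})

test_that("increasing noise never improves expected k-means accuracy", {
  mean_acc <- sapply(c(0.02, 0.1, 0.3), function(ns) {
    mean(sapply(1:10, function(s) {
      pool <- small_pool(120, noise_sd = ns, seed = s)
      fs <- pca_features(pool)
      acc_of(fs$gt_labels,
             run_supervised(algorithm_spec("kmeans", seed = s), fs, 3))
    }))
  })
  expect_true(all(diff(mean_acc) <= 0))
})

test_that("a zero-noise pipeline reaches perfect accuracy", {
  # zero noise collapses each class to a point, so the pool is rank 2 and
  # PCA refuses it; the wavelet features carry this degenerate case
  pool <- small_pool(90, noise_sd = 0, seed = 8)
  expect_error(pca_features(pool), "non-degenerate variance directions")
  fs <- wavelet_features(pool)
  p <- run_supervised(algorithm_spec("kmeans", seed = 1), fs, 3)
  expect_equal(acc_of(fs$gt_labels, p), 100)
})
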