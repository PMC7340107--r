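test_that("a perfect partition fills the confusion-matrix diagonal", {
  gt <- rep(1:3, c(10, 20, 30))
  cm <- match_confusion_matrix(gt, gt)
  expect_equal(diag(cm$counts), c(10, 20, 30))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)
  expect_identical(cm$discarded, 0L)
  expect_equal(accuracy(cm), 100)
})

test_that("best-match assignment follows descending overlap with tie-breaks", {
  gt <- c(1, 1, 1, 2, 2, 3)
  cl <- c(5, 5, 2, 2, 2, 9)
  cm <- match_confusion_matrix(gt, cl)
  # clusters re-indexed 2->1, 5->2, 9->3; classes match 1->5, 2->2, 3->9
  expect_identical(cm$mapping, c(2L, 1L, 3L))
  expect_equal(diag(cm$counts), c(2, 2, 1))
  expect_equal(cm$counts[1, 2], 1) # class-1 spike inside class-2's cluster
  expect_equal(accuracy(cm), 100 * 5 / 6)
})

test_that("a single cluster over balanced classes captures one class only", {
  gt <- rep(1:3, each = 1000)
  cm <- match_confusion_matrix(gt, rep(1, 3000))
  expect_equal(sum(diag(cm$counts) > 0), 1)
  expect_equal(max(diag(cm$counts)), 1000)
  expect_equal(round(accuracy(cm), 1), 33.3)
})

test_that("extra clusters are discarded but stay on the books", {
  gt <- c(1, 1, 2, 2)
  cl <- c(1, 3, 2, 4) # 4 clusters for 2 classes
  cm <- match_confusion_matrix(gt, cl)
  expect_equal(sum(cm$counts) + cm$discarded, 4)
  expect_identical(cm$discarded, 2L)
})

test_that("the empty partition scores zero everywhere", {
  gt <- rep(1:3, each = 5)
  empty <- spike_partition(NULL, n_points = 15)
  cm <- match_confusion_matrix(gt, empty)
  expect_true(all(cm$counts == 0))
  expect_equal(accuracy(cm), 0)
  expect_equal(rand_index(gt, empty), 0)
  jac <- jaccard_index(gt, empty)
  expect_equal(as.numeric(jac), 0)
  expect_true(attr(jac, "no_index"))
})

test_that("greedy matching never beats the exhaustive optimal assignment", {
  set.seed(20)
  for (rep_i in 1:20) {
    m <- sample(20:60, 1)
    gt <- sample(1:4, m, replace = TRUE)
    cl <- sample(1:sample(2:6, 1), m, replace = TRUE)
    g <- match_confusion_matrix(gt, cl, method = "greedy")
    o <- match_confusion_matrix(gt, cl, method = "optimal")
    expect_lte(sum(diag(g$counts)), sum(diag(o$counts)))
  }
})

test_that("Rand and Jaccard match hand-enumerated pair counts", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 2 / 6)
  expect_equal(as.numeric(jaccard_index(c(1, 1, 2, 2), c(1, 2, 1, 2))), 0)
  expect_equal(rand_index(1:4, 1:4), 1)
  expect_equal(as.numeric(jaccard_index(rep(1:2, 3), rep(1:2, 3))), 1)
  # single all-encompassing cluster on balanced 3 classes
  gt <- rep(1:3, each = 1000)
  expect_equal(round(rand_index(gt, rep(1, 3000)), 2), 0.33)
})

test_that("pair-counting indices equal exhaustive enumeration", {
  set.seed(21)
  for (rep_i in 1:100) {
    m <- sample(10:200, 1)
    gt <- sample(1:4, m, replace = TRUE)
    cl <- sample(1:5, m, replace = TRUE)
    o <- pair_oracle(gt, cl)
    expect_equal(rand_index(gt, cl), o$rand, tolerance = 1e-12)
    j <- jaccard_index(gt, cl)
    if (is.na(o$jaccard)) expect_true(attr(j, "no_index"))
    else expect_equal(as.numeric(j), o$jaccard, tolerance = 1e-12)
  }
})

test_that("internal indices reproduce the 1-D hand example", {
  x <- matrix(c(0, 2, 10, 14), ncol = 1)
  labels <- c(1, 1, 2, 2)
  expect_equal(ball_hall(x, labels), 2.5)
  expect_equal(trace_w(x, labels), 10)
  expect_equal(davies_bouldin(x, labels), 3 / 11)
})

test_that("internal indices vanish for singleton clusters", {
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(ball_hall(x, 1:4), 0)
  expect_equal(trace_w(x, 1:4), 0)
  expect_equal(davies_bouldin(x[1:2, ], 1:2), 0)
})

test_that("internal indices match brute-force double-loop oracles", {
  set.seed(22)
  for (rep_i in 1:5) {
    x <- matrix(rnorm(150), 50, 3)
    labels <- sample(1:4, 50, replace = TRUE)
    expect_equal(ball_hall(x, labels), bh_oracle(x, labels), tolerance = 1e-9)
    expect_equal(trace_w(x, labels), trw_oracle(x, labels), tolerance = 1e-9)
    expect_equal(davies_bouldin(x, labels), db_oracle(x, labels),
                 tolerance = 1e-9)
  }
})

test_that("Trace-W relates to Ball-Hall on equal-sized clusters", {
  set.seed(23)
  x <- matrix(rnorm(120), 40, 3)
  labels <- rep(1:2, each = 20)
  expect_equal(trace_w(x, labels), 2 * 20 * ball_hall(x, labels),
               tolerance = 1e-9)
})

test_that("Davies-Bouldin is scale invariant; Ball-Hall and Trace-W are not", {
  set.seed(24)
  x <- matrix(rnorm(90), 30, 3)
  labels <- rep(1:3, each = 10)
  expect_equal(davies_bouldin(x * 7, labels), davies_bouldin(x, labels),
               tolerance = 1e-9)
  expect_equal(ball_hall(x * 7, labels), 49 * ball_hall(x, labels),
               tolerance = 1e-9)
  expect_error(davies_bouldin(x, rep(1, 30)), "at least 2")
})

test_that("normalization maps the reference to 1 and stays in [0, 1]", {
  expect_equal(normalize_internal(c(a = 0.2, b = 0.5, c = 1.0), 1.0),
               c(a = 0, b = 0.375, c = 1))
  expect_equal(unname(normalize_internal(c(x = 4), 4)), 1)
  expect_equal(unname(normalize_internal(c(2, 2, 2), 2)), c(1, 1, 1))
  # reference inside the range set keeps every score bounded
  set.seed(25)
  for (rep_i in 1:20) {
    v <- rnorm(8, sd = 10)
    r <- rnorm(1, sd = 10)
    nii <- normalize_internal(v, r)
    expect_true(all(nii >= 0 & nii <= 1))
  }
})

test_that("the inverted RMSE follows its closed form", {
  expect_equal(inverted_rmse(rep(1, 6)), list(rmse = 0, inverted = 1))
  ir <- inverted_rmse(c(1, 1, 1, 1, 1, 0.4))
  expect_equal(ir$rmse, sqrt(0.06))
  expect_equal(ir$inverted, 1 - sqrt(0.06))
  expect_equal(inverted_rmse(rep(0, 6))$inverted, 0)
  expect_error(inverted_rmse(1:3 / 3, g = c(1, 1)), "differ in length")
})

test_that("categories bin ranked algorithms into quintiles below ideal", {
  cons <- data.frame(algorithm = c("ground-truth", paste0("a", 1:10)),
                     inverted = c(1, seq(0.95, 0.05, length.out = 10)))
  out <- categorize(cons)
  expect_identical(as.character(out$category[1]), "ideal")
  expect_identical(as.vector(table(out$category[-1])[-1]), rep(2L, 5))
  # monotone: better inverted never maps to a worse category
  expect_true(all(diff(as.integer(out$category[-1])) >= 0))
})

test_that("fixed-threshold categorization honours its breaks", {
  cons <- data.frame(algorithm = c("ground-truth", "good", "bad"),
                     inverted = c(1, 0.92, 0.1))
  out <- categorize(cons, breaks = c(0.9, 0.7, 0.5, 0.3))
  expect_identical(as.character(out$category),
                   c("ideal", "most-compatible", "non-compatible"))
})

test_that("index consistency is the population variance of the NII triple", {
  expect_equal(index_consistency(c(1, 1, 1)), 0)
  expect_equal(index_consistency(c(1, 0.5, 0)), 1 / 6, tolerance = 1e-12)
  expect_equal(index_consistency(c(0, 1, 0.5)), index_consistency(c(1, 0.5, 0)))
  expect_true(is.na(index_consistency(c(1, NA, 0))))
  expect_error(index_consistency(c(1, 0)), "exactly")
})

test_that("partition-count selection applies each rule with tie-breaks", {
  expect_equal(select_partition(c(5, 1, 4, 6), counts = 2:5, rule = "min"), 3)
  expect_equal(select_partition(c(10, 6, 5, 4.8), counts = 2:5,
                                rule = "max_second_diff"), 3)
  expect_equal(select_partition(rep(2, 5), counts = 2:6, rule = "min"), 2)
  expect_equal(select_partition(rep(2, 5), counts = 2:6,
                                rule = "max_second_diff"), 2)
  expect_error(select_partition(c(1, 2), rule = "max_second_diff"),
               "length >= 3")
})

test_that("all scores are invariant to cluster relabeling", {
  set.seed(26)
  x <- matrix(rnorm(180), 60, 3)
  gt <- sample(1:3, 60, replace = TRUE)
  cl <- sample(1:4, 60, replace = TRUE)
  relab <- c(4, 1, 3, 2)[cl] # a permutation of the label alphabet
  expect_equal(rand_index(gt, cl), rand_index(gt, relab))
  expect_equal(as.numeric(jaccard_index(gt, cl)),
               as.numeric(jaccard_index(gt, relab)))
  expect_equal(accuracy(match_confusion_matrix(gt, cl)),
               accuracy(match_confusion_matrix(gt, relab)))
  expect_equal(ball_hall(x, cl), ball_hall(x, relab))
  expect_equal(trace_w(x, cl), trace_w(x, relab))
  expect_equal(davies_bouldin(x, cl), davies_bouldin(x, relab))
})

test_that("accuracy is 100 exactly when the partition is ground truth up to relabeling", {
  set.seed(27)
  gt <- sample(1:3, 40, replace = TRUE)
  expect_equal(acc_of(gt, c(3, 1, 2)[gt]), 100)
  # merging two classes cannot reach 100
  expect_lt(acc_of(gt, pmin(gt, 2)), 100)
  # splitting one class cannot reach 100 either
  split <- gt
  split[gt == 1] <- sample(c(1, 4), sum(gt == 1), replace = TRUE)
  if (length(unique(split[gt == 1])) > 1) expect_lt(acc_of(gt, split), 100)
})
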