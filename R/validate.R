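# The scoring stack: best-match confusion matrix and accuracy, external
# indices (Rand, Jaccard), internal indices (Ball-Hall, Trace-W,
# Davies-Bouldin), ground-truth referenced normalization, inverted-RMSE
# consistency across feature-sets, compatibility categories, and the
# index-consistency diagnostic.

#' Best-match confusion matrix between ground truth and a partition
#'
#' Builds the class-by-cluster co-occurrence table, then matches
#' ground-truth classes to clusters one-to-one, greedily by descending
#' overlap count (ties: lower class label, then lower cluster label).
#' Matched clusters occupy the diagonal; a class's spikes that landed in a
#' *different matched* cluster fill the off-diagonal cell in that cluster's
#' matched column. Spikes in unmatched clusters (an algorithm that produced
#' too many clusters) cannot be fit into the L x L table and are counted in
#' `discarded`, so totals stay auditable. The empty partition yields the
#' all-zero matrix.
#'
#' An exhaustive optimal-assignment mode (`method = "optimal"`) maximizes
#' the diagonal sum over all one-to-one assignments; it exists to quantify
#' the greedy gap and is practical for small class counts only.
#'
#' @param gt_labels integer ground-truth class per spike (`1..L`).
#' @param partition a [spike_partition] (or raw label vector).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return a `confusion_matrix`: list with `counts` (L x L), `mapping`
#'   (class -> matched cluster id, `NA` if unmatched), `discarded`, and
#'   `M`.
#' @export
match_confusion_matrix <- function(gt_labels, partition,
                                   method = c("greedy", "optimal")) {
  method <- match.arg(method)
  partition <- as_partition(partition, n_points = length(gt_labels))
  gt_labels <- as.integer(gt_labels)
  if (length(gt_labels) != length(partition$labels))
    stop("ground truth and partition differ in length (",
         length(gt_labels), " vs ", length(partition$labels), ")")
  L <- max(gt_labels)
  counts <- matrix(0L, L, L)
  mapping <- rep(NA_integer_, L)
  M <- length(gt_labels)
  if (partition$empty) {
    return(structure(list(counts = counts, mapping = mapping,
                          discarded = 0L, M = M),
                     class = "confusion_matrix"))
  }
  k <- partition$k
  cont <- matrix(0L, L, k)
  for (i in seq_len(M))
    cont[gt_labels[i], partition$labels[i]] <-
      cont[gt_labels[i], partition$labels[i]] + 1L

  if (method == "greedy") {
    ord <- order(-as.vector(cont),
                 rep(seq_len(L), k),        # tie: lower class label
                 rep(seq_len(k), each = L)) # then lower cluster label
    free_class <- rep(TRUE, L); free_clust <- rep(TRUE, k)
    for (o in ord) {
      if (cont[o] == 0L) break
      l <- (o - 1L) %% L + 1L
      cc <- (o - 1L) %/% L + 1L
      if (free_class[l] && free_clust[cc]) {
        mapping[l] <- cc
        free_class[l] <- FALSE; free_clust[cc] <- FALSE
      }
    }
  } else {
    mapping <- optimal_assignment(cont)
  }

  matched_clusters <- mapping[!is.na(mapping)]
  class_of_cluster <- rep(NA_integer_, k)
  class_of_cluster[matched_clusters] <- which(!is.na(mapping))
  for (l in seq_len(L)) for (cc in seq_len(k)) {
    if (!is.na(class_of_cluster[cc]))
      counts[l, class_of_cluster[cc]] <- cont[l, cc]
  }
  discarded <- sum(cont[, setdiff(seq_len(k), matched_clusters), drop = FALSE])
  structure(list(counts = counts, mapping = mapping,
                 discarded = as.integer(discarded), M = M),
            class = "confusion_matrix")
}

# Exhaustive one-to-one assignment maximizing the diagonal sum; L! search,
# intended for auditing the greedy rule on small L.
optimal_assignment <- function(cont) {
  L <- nrow(cont); k <- ncol(cont)
  slots <- utils::combn(k, min(L, k), simplify = FALSE)
  best <- rep(NA_integer_, L); best_sum <- -1L
  classes <- utils::combn(L, min(L, k), simplify = FALSE)
  for (cls in classes) for (sl in slots) {
    for (perm in perms(sl)) {
      s <- sum(cont[cbind(cls, perm)])
      if (s > best_sum) {
        best_sum <- s
        best <- rep(NA_integer_, L)
        best[cls] <- perm
      }
    }
  }
  best
}

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, M=%d, discarded=%d\n",
              nrow(x$counts), x$M, x$discarded))
  print(x$counts)
  invisible(x)
}

#' Sorting accuracy from a confusion matrix
#'
#' The percentage of spikes sorted without confusion: 100 times the
#' diagonal sum of the best-match confusion matrix over the total spike
#' count `M` (the denominator is all spikes, including any discarded into
#' unmatched clusters).
#'
#' @param cm a `confusion_matrix`.
#' @param M total spike count (defaults to the one recorded in `cm`).
#' @return accuracy in `[0, 100]`.
#' @export
accuracy <- function(cm, M = cm$M) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (M <= 0) stop("M must be positive")
  100 * sum(diag(cm$counts)) / M
}

# Pair-counting sufficient statistics from the contingency table.
pair_counts <- function(gt_labels, labels) {
  cont <- table(gt_labels, labels)
  n <- length(gt_labels)
  total <- choose(n, 2)
  tp <- sum(choose(cont, 2))                 # same class & same cluster
  same_gt <- sum(choose(rowSums(cont), 2))   # same class
  same_cl <- sum(choose(colSums(cont), 2))   # same cluster
  list(total = total, tp = tp, fn = same_gt - tp, fp = same_cl - tp)
}

#' Rand index against ground truth
#'
#' Pair-counting Rand index: the fraction of point pairs on which the
#' partition and the ground truth agree (together in both, or apart in
#' both). The empty partition — an algorithm that failed to produce any
#' cluster — scores 0, the worst case.
#'
#' @param gt_labels integer ground-truth classes.
#' @param partition a [spike_partition] or raw label vector.
#' @return index in `[0, 1]`.
#' @export
rand_index <- function(gt_labels, partition) {
  partition <- as_partition(partition, n_points = length(gt_labels))
  if (length(gt_labels) != length(partition$labels))
    stop("ground truth and partition differ in length")
  if (partition$empty) return(0)
  pc <- pair_counts(gt_labels, partition$labels)
  (pc$total - pc$fn - pc$fp) / pc$total
}

#' Jaccard index against ground truth
#'
#' Pair-counting Jaccard index `TP / (TP + FP + FN)`. When no pair is
#' positive in either partition, or the partition is empty, no index can be
#' produced: the value is 0 with attribute `no_index = TRUE` so reports can
#' flag the cell rather than mistake it for a measured zero.
#'
#' @inheritParams rand_index
#' @return index in `[0, 1]`, possibly flagged with `attr(, "no_index")`.
#' @export
jaccard_index <- function(gt_labels, partition) {
  partition <- as_partition(partition, n_points = length(gt_labels))
  if (length(gt_labels) != length(partition$labels))
    stop("ground truth and partition differ in length")
  if (partition$empty) return(structure(0, no_index = TRUE))
  pc <- pair_counts(gt_labels, partition$labels)
  denom <- pc$tp + pc$fp + pc$fn
  if (denom == 0) return(structure(0, no_index = TRUE))
  pc$tp / denom
}

cluster_stats <- function(x, labels) {
  ks <- sort(unique(labels))
  lapply(ks, function(kk) {
    pts <- x[labels == kk, , drop = FALSE]
    ctr <- colMeans(pts)
    d2 <- rowSums((pts - rep(ctr, each = nrow(pts)))^2)
    list(center = ctr, d2 = d2, n = nrow(pts))
  })
}

#' Ball-Hall index
#'
#' Mean over clusters of the within-cluster mean squared Euclidean distance
#' to the cluster barycentre. Lower is tighter; defined for any `k >= 1`
#' (a single cluster measures global scatter).
#'
#' @param fs a [feature_set] (or plain numeric matrix).
#' @param partition a [spike_partition] or raw label vector.
#' @return a non-negative scalar.
#' @export
ball_hall <- function(fs, partition) {
  x <- if (inherits(fs, "feature_set")) fs$matrix else as.matrix(fs)
  partition <- as_partition(partition, n_points = nrow(x))
  if (partition$empty) stop("internal indices are undefined for the empty partition")
  st <- cluster_stats(x, partition$labels)
  mean(vapply(st, function(s) mean(s$d2), 0))
}

#' Trace of the pooled within-cluster scatter (Trace-W)
#'
#' Sum over all points of the squared Euclidean distance to their cluster
#' barycentre — unnormalized, so it grows with the spike count `M` (its raw
#' values typically range in the thousands on full benchmark pools, which
#' is why scores are normalized before cross-feature-set comparison).
#'
#' @inheritParams ball_hall
#' @return a non-negative scalar.
#' @export
trace_w <- function(fs, partition) {
  x <- if (inherits(fs, "feature_set")) fs$matrix else as.matrix(fs)
  partition <- as_partition(partition, n_points = nrow(x))
  if (partition$empty) stop("internal indices are undefined for the empty partition")
  st <- cluster_stats(x, partition$labels)
  sum(vapply(st, function(s) sum(s$d2), 0))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst ratio of summed within-cluster
#' dispersions to between-centroid distance:
#' `(1/k) * sum_c max_{c' != c} (delta_c + delta_c') / d(center_c, center_c')`
#' with `delta` the mean Euclidean distance of members to their centroid.
#' Lower is better. Requires `k >= 2`; coincident centroids make the ratio
#' undefined and return `NaN` with a warning (callers flag the cell).
#'
#' @inheritParams ball_hall
#' @return a non-negative scalar (or `NaN` when centroids coincide).
#' @export
davies_bouldin <- function(fs, partition) {
  x <- if (inherits(fs, "feature_set")) fs$matrix else as.matrix(fs)
  partition <- as_partition(partition, n_points = nrow(x))
  if (partition$empty) stop("internal indices are undefined for the empty partition")
  if (partition$k < 2) stop("Davies-Bouldin requires at least 2 clusters")
  st <- cluster_stats(x, partition$labels)
  k <- length(st)
  delta <- vapply(st, function(s) mean(sqrt(s$d2)), 0)
  centers <- matrix(unlist(lapply(st, function(s) s$center)),
                    nrow = k, byrow = TRUE)
  dc <- as.matrix(stats::dist(centers))
  if (any(dc[upper.tri(dc)] == 0)) {
    warning("coincident cluster centroids: Davies-Bouldin undefined")
    return(NaN)
  }
  r <- vapply(seq_len(k), function(i)
    max(vapply(setdiff(seq_len(k), i), function(jx)
      (delta[i] + delta[jx]) / dc[i, jx], 0)), 0)
  mean(r)
}

#' Normalize internal indices against a ground-truth reference
#'
#' For one (criterion, feature-set) pair, maps each algorithm's raw
#' internal index `i` to `1 - |r - i| / (max(I) - min(I))`, where `r` is
#' the ground-truth partition's index for that pair and the range is taken
#' over the observed values *including* `r` — so the normalized index (NII)
#' is always in `[0, 1]` and the ground truth scores exactly 1. When all
#' values coincide, the score is 1 where `i == r` and 0 otherwise.
#'
#' @param values named numeric vector of raw indices, one per algorithm.
#' @param reference the ground-truth raw index `r`.
#' @return named numeric vector of NII values in `[0, 1]`.
#' @export
normalize_internal <- function(values, reference) {
  if (length(values) == 0L) stop("no index values to normalize")
  rng <- max(c(values, reference)) - min(c(values, reference))
  if (rng == 0) return(ifelse(values == reference, 1, 0))
  1 - abs(reference - values) / rng
}

#' Inverted-RMSE consistency score across feature-sets
#'
#' An algorithm's external indices `e_f` across the `N` feature-sets are
#' compared with the ideal value 1 (the ground-truth score `g_f`):
#' `RMSE = sqrt( sum_f (g_f - e_f)^2 / N )`, then inverted to
#' `1 - RMSE` so 1 means perfectly consistent ideal performance and 0 the
#' worst case.
#'
#' @param e numeric external indices per feature-set, each in `[0, 1]`.
#' @param g ground-truth targets (default all 1).
#' @return list with `rmse` and `inverted`.
#' @export
inverted_rmse <- function(e, g = rep(1, length(e))) {
  if (length(e) != length(g))
    stop("e and g differ in length (", length(e), " vs ", length(g), ")")
  rmse <- sqrt(sum((g - e)^2) / length(e))
  list(rmse = rmse, inverted = 1 - rmse)
}

#' Compatibility categories from consistency scores
#'
#' The ground-truth pseudo-algorithm is `"ideal"`; the remaining algorithms
#' are ranked by inverted RMSE and binned into `"most-compatible"`,
#' `"compatible"`, `"average"`, `"least-compatible"` and
#' `"non-compatible"` — by rank quintiles (default) or by fixed inverted-
#' RMSE thresholds (`breaks`, descending cut points of length 4).
#'
#' @param consistency data frame with columns `algorithm` and `inverted`
#'   (see [evaluate_all()]), including the `"ground-truth"` row.
#' @param breaks optional numeric thresholds `c(b1, b2, b3, b4)`:
#'   `inverted >= b1` is most-compatible, `>= b2` compatible, `>= b3`
#'   average, `>= b4` least-compatible, below non-compatible.
#' @return the data frame with a `category` column added.
#' @export
categorize <- function(consistency, breaks = NULL) {
  stopifnot(is.data.frame(consistency),
            all(c("algorithm", "inverted") %in% names(consistency)))
  cats <- c("most-compatible", "compatible", "average",
            "least-compatible", "non-compatible")
  out <- consistency
  out$category <- NA_character_
  is_gt <- out$algorithm == "ground-truth"
  out$category[is_gt] <- "ideal"
  rest <- which(!is_gt)
  if (length(rest)) {
    inv <- out$inverted[rest]
    if (is.null(breaks)) {
      r <- rank(-inv, ties.method = "min")
      bin <- floor((r - 1) * 5 / length(rest)) + 1L # rank 1 -> top category
    } else {
      stopifnot(length(breaks) == 4L, !is.unsorted(rev(breaks)))
      bin <- 5L - findInterval(inv, rev(breaks))
      bin[bin < 1L] <- 1L
    }
    out$category[rest] <- cats[bin]
  }
  out$category <- factor(out$category, levels = c("ideal", cats))
  out
}

#' Index-consistency diagnostic
#'
#' The population variance of the three normalized internal indices
#' (Ball-Hall, Trace-W, Davies-Bouldin) for one algorithm-featureset pair.
#' High variance — disagreement among the internal indices — flags an
#' incompatible algorithm; compatible algorithms show near-zero variance.
#'
#' @param nii numeric vector of exactly 3 NII values.
#' @return the population variance (non-negative scalar), or `NA` when any
#'   index is missing.
#' @export
index_consistency <- function(nii) {
  if (length(nii) != 3L)
    stop("index consistency needs exactly the 3 NII values, got ", length(nii))
  if (any(is.na(nii))) return(NA_real_)
  mean((nii - mean(nii))^2)
}

#' Partition-count selection from an index series
#'
#' Applies a selection rule to internal-index values computed over a range
#' of candidate partition counts. Rules: `"min"`, `"max"`,
#' `"max_second_diff"`, `"min_second_diff"` (second differences
#' `x[j-1] - 2 x[j] + x[j+1]`, defined at interior positions), and
#' `"max_diff_left"` (`x[j-1] - x[j]`). The conventional defaults are
#' minimum score for Davies-Bouldin and maximum second difference for
#' Ball-Hall and Trace-W. Ties break toward the smaller count.
#'
#' @param values index value per candidate.
#' @param counts candidate partition counts (default `seq_along(values)`).
#' @param rule selection rule.
#' @return the chosen count.
#' @export
select_partition <- function(values,
                             counts = seq_along(values),
                             rule = c("min", "max", "max_second_diff",
                                      "min_second_diff", "max_diff_left")) {
  rule <- match.arg(rule)
  stopifnot(length(values) == length(counts))
  n <- length(values)
  if (rule %in% c("max_second_diff", "min_second_diff") && n < 3L)
    stop("second-difference rules need a series of length >= 3")
  if (rule == "max_diff_left" && n < 2L)
    stop("difference-to-left needs a series of length >= 2")
  if (all(values == values[1L])) # degenerate series carries no information
    return(counts[which.min(counts)])
  score <- switch(rule,
    min = -values,
    max = values,
    max_second_diff = c(-Inf, values[1:(n - 2)] - 2 * values[2:(n - 1)] +
                          values[3:n], -Inf),
    min_second_diff = c(-Inf, -(values[1:(n - 2)] - 2 * values[2:(n - 1)] +
                                  values[3:n]), -Inf),
    max_diff_left = c(-Inf, values[1:(n - 1)] - values[2:n]))
  best <- which(score == max(score))
  counts[best[which.min(counts[best])]]
}
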