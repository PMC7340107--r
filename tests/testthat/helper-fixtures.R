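# Shared fixtures, built in code at test time.

# Small low-similarity 3-class pool.
small_pool <- function(n_spikes = 150, noise_sd = 0.05, seed = 1,
                       similarity = "low", n_classes = 3) {
  simulate_waveform_pool(sim_config(n_classes = n_classes,
                                    n_spikes = n_spikes,
                                    similarity = similarity,
                                    noise_sd = noise_sd, seed = seed))
}

# Accuracy of a partition against ground truth, through the confusion path.
acc_of <- function(gt, partition) {
  accuracy(match_confusion_matrix(gt, partition))
}

# Exhaustive pair-enumeration oracles for Rand and Jaccard, independent of
# the contingency-table implementation.
pair_oracle <- function(g, c_labels) {
  same_g <- outer(g, g, "==")
  same_c <- outer(c_labels, c_labels, "==")
  up <- upper.tri(same_g)
  tp <- sum(same_g[up] & same_c[up])
  fp <- sum(!same_g[up] & same_c[up])
  fn <- sum(same_g[up] & !same_c[up])
  tn <- sum(!same_g[up] & !same_c[up])
  list(rand = (tp + tn) / (tp + tn + fp + fn),
       jaccard = if (tp + fp + fn == 0) NA_real_ else tp / (tp + fp + fn))
}

# Brute-force internal index oracles (double loops, no shared code with
# the implementation).
bh_oracle <- function(x, labels) {
  mean(sapply(sort(unique(labels)), function(k) {
    pts <- x[labels == k, , drop = FALSE]
    ctr <- colMeans(pts)
    mean(apply(pts, 1, function(p) sum((p - ctr)^2)))
  }))
}
trw_oracle <- function(x, labels) {
  sum(sapply(sort(unique(labels)), function(k) {
    pts <- x[labels == k, , drop = FALSE]
    ctr <- colMeans(pts)
    sum(apply(pts, 1, function(p) sum((p - ctr)^2)))
  }))
}
db_oracle <- function(x, labels) {
  ks <- sort(unique(labels))
  ctr <- t(sapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE])))
  delta <- sapply(seq_along(ks), function(i) {
    pts <- x[labels == ks[i], , drop = FALSE]
    mean(apply(pts, 1, function(p) sqrt(sum((p - ctr[i, ])^2))))
  })
  mean(sapply(seq_along(ks), function(i) {
    max(sapply(setdiff(seq_along(ks), i), function(j)
      (delta[i] + delta[j]) / sqrt(sum((ctr[i, ] - ctr[j, ])^2))))
  }))
}
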