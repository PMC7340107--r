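# The two canonical feature representations (3 principal components; 10
# Haar wavelet coefficients ranked by deviation from normality) and the
# KNN graph export for graph-based clusterers.

#' PCA feature-set (d = 3)
#'
#' Mean-centers the pooled waveforms, computes the three principal
#' components of largest variance, and projects every waveform onto them.
#' The fraction of total variance those components cover is reported in
#' `metadata$variance_fraction` (the curated benchmark pools reach ~95%;
#' arbitrary pools may not — the fraction is reported, never enforced).
#'
#' @param pool a [waveform_pool] with `M >= 4`.
#' @param label optional dataset tag (e.g. `"Epca"`).
#' @return a [feature_set] of kind `"pca"`, M x 3.
#' @export
pca_features <- function(pool, label = NA_character_) {
  stopifnot(inherits(pool, "waveform_pool"))
  x <- pool$waveforms
  if (nrow(x) < 4L) stop("PCA needs at least 4 waveforms, got ", nrow(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank_ <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (rank_ < 3L)
    stop("waveform pool has only ", rank_,
         " non-degenerate variance directions; 3 are required")
  proj <- pc$x[, 1:3, drop = FALSE]
  vf <- sum(pc$sdev[1:3]^2) / sum(pc$sdev^2)
  feature_set(proj, kind = "pca", gt_labels = pool$gt_labels, label = label,
              metadata = list(variance_fraction = vf))
}

#' Orthonormal Haar discrete wavelet transform
#'
#' Multi-level Haar pyramid of a 64-sample waveform: at each level the
#' signal is split into pairwise averages (approximation) and differences
#' (detail), both scaled by `1/sqrt(2)` so the transform is orthonormal
#' (energy preserving). The output concatenates the level-`levels`
#' approximation followed by the detail bands from coarsest to finest —
#' the same length as the input.
#'
#' @param waveform numeric vector whose length is divisible by
#'   `2^levels`.
#' @param levels decomposition depth (default 5).
#' @return numeric vector of wavelet coefficients, same length as input.
#' @export
haar_dwt <- function(waveform, levels = 5L) {
  n <- length(waveform)
  if (n %% 2^levels != 0L)
    stop("waveform length ", n, " is not divisible by 2^", levels)
  approx <- waveform
  details <- list()
  for (l in seq_len(levels)) {
    odd <- approx[seq(1L, length(approx), 2L)]
    even <- approx[seq(2L, length(approx), 2L)]
    details[[l]] <- (odd - even) / sqrt(2)
    approx <- (odd + even) / sqrt(2)
  }
  c(approx, unlist(rev(details)))
}

#' Deviation from normality of a sample (Lilliefors-style KS statistic)
#'
#' Standardizes the sample by its own mean and standard deviation and
#' returns the supremum over sample points of the distance between the
#' empirical CDF and the standard normal CDF. Only the ranking of
#' coefficients matters downstream, so no p-value is computed. A
#' zero-variance sample carries no information and returns 0 with a
#' warning.
#'
#' @param values numeric sample, length >= 8.
#' @return statistic in `[0, 1]`.
#' @export
ks_normality_deviation <- function(values) {
  n <- length(values)
  if (n < 8L) stop("need at least 8 values, got ", n)
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero-variance sample: normality deviation undefined, returning 0")
    return(0)
  }
  z <- sort((values - mean(values)) / s)
  p <- stats::pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1L) / n)
}

#' Wavelet feature-set (d = 10)
#'
#' Decomposes every waveform with a 5-level Haar DWT, scores each of the 64
#' coefficient positions across the pool by deviation from normality
#' ([ks_normality_deviation()]) — multimodal coefficients separate spike
#' classes — and keeps the raw values of the ten highest-scoring
#' coefficients (ties broken toward the lower coefficient index). The
#' selected indices and their scores are recorded in metadata. A degenerate
#' pool where every coefficient scores 0 falls back to the first ten
#' indices with a warning.
#'
#' @param pool a [waveform_pool] with `M >= 8`.
#' @param label optional dataset tag (e.g. `"Eks"`).
#' @param levels Haar decomposition depth.
#' @return a [feature_set] of kind `"wavelet"`, M x 10.
#' @export
wavelet_features <- function(pool, label = NA_character_, levels = 5L) {
  stopifnot(inherits(pool, "waveform_pool"))
  x <- pool$waveforms
  if (nrow(x) < 8L) stop("wavelet feature selection needs M >= 8, got ", nrow(x))
  coeffs <- t(apply(x, 1L, haar_dwt, levels = levels))
  dev <- numeric(ncol(coeffs))
  for (jc in seq_len(ncol(coeffs))) {
    dev[jc] <- if (stats::sd(coeffs[, jc]) == 0) 0 else
      ks_normality_deviation(coeffs[, jc])
  }
  if (all(dev == 0)) {
    warning("all coefficients have zero normality deviation; ",
            "selecting the first 10 coefficient indices")
    sel <- 1:10
  } else {
    sel <- order(-dev, seq_along(dev))[1:10]
  }
  feature_set(coeffs[, sel, drop = FALSE], kind = "wavelet",
              gt_labels = pool$gt_labels, label = label,
              metadata = list(selected_indices = sel,
                              deviations = dev[sel]))
}

#' K-nearest-neighbor graph of a feature-set
#'
#' For each point, its `K` nearest other points by Euclidean distance, as a
#' directed weighted edge list — the input format of graph-based
#' clusterers. Neighbor ties are broken toward the lower point index.
#'
#' @param fs a [feature_set] with more points than `K`.
#' @param K out-degree per node (default 11).
#' @return a `knn_graph`: list with `edges` (data frame `source`, `target`,
#'   `weight`; 1-based node ids) and `K`.
#' @export
knn_graph <- function(fs, K = 11L) {
  stopifnot(inherits(fs, "feature_set"))
  m <- nrow(fs$matrix)
  if (m <= K) stop("need more points than K: M = ", m, ", K = ", K)
  d <- as.matrix(stats::dist(fs$matrix))
  src <- integer(m * K); tgt <- integer(m * K); w <- numeric(m * K)
  for (i in seq_len(m)) {
    di <- d[i, ]
    di[i] <- Inf
    nn <- order(di, seq_len(m))[seq_len(K)]
    idx <- ((i - 1L) * K + 1L):(i * K)
    src[idx] <- i; tgt[idx] <- nn; w[idx] <- di[nn]
  }
  structure(list(edges = data.frame(source = src, target = tgt, weight = w),
                 K = as.integer(K)),
            class = "knn_graph")
}

#' Write a KNN graph as a plain-text edge list
#'
#' One `source target weight` line per directed edge, whitespace-separated,
#' node ids 1-based.
#'
#' @param graph a `knn_graph`.
#' @param path output `.txt` path.
#' @return `path`, invisibly.
#' @export
write_knn_graph <- function(graph, path) {
  stopifnot(inherits(graph, "knn_graph"))
  utils::write.table(graph$edges, path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
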