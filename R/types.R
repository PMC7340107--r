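# Core S3 containers shared across the pipeline.

#' Construct a ground-truthed recording
#'
#' A single-channel voltage trace plus, optionally, the ground-truth spike
#' times (sample indices into the trace) and spike class labels that
#' benchmark containers carry.
#'
#' @param samples numeric voltage trace (arbitrary units).
#' @param sampling_rate sampling rate in Hz.
#' @param gt_times integer sample indices of spike events, strictly
#'   increasing, or `NULL` when no ground truth is available.
#' @param gt_labels integer class label per event in `1..L`, same length as
#'   `gt_times`, or `NULL`.
#' @return an object of class `spike_recording`.
#' @export
spike_recording <- function(samples, sampling_rate = 24000,
                            gt_times = NULL, gt_labels = NULL) {
  samples <- as.numeric(samples)
  stopifnot(is.numeric(sampling_rate), sampling_rate > 0)
  if (!is.null(gt_times)) {
    gt_times <- as.integer(round(gt_times))
    if (length(gt_times) > 1 && any(diff(gt_times) <= 0))
      stop("ground-truth spike times must be strictly increasing")
    if (is.null(gt_labels))
      stop("gt_labels must accompany gt_times")
    gt_labels <- as.integer(gt_labels)
    if (length(gt_labels) != length(gt_times))
      stop("gt_times and gt_labels differ in length (",
           length(gt_times), " vs ", length(gt_labels), ")")
    if (length(gt_labels) && any(gt_labels < 1L))
      stop("gt_labels must be positive integers (1..L)")
  } else if (!is.null(gt_labels)) {
    stop("gt_times must accompany gt_labels")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 gt_times = gt_times, gt_labels = gt_labels),
            class = "spike_recording")
}

#' @export
print.spike_recording <- function(x, ...) {
  cat(sprintf("<spike_recording> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (!is.null(x$gt_times))
    cat(sprintf("  ground truth: %d events, %d classes\n",
                length(x$gt_times), length(unique(x$gt_labels))))
  else cat("  ground truth: none\n")
  invisible(x)
}

#' Construct a waveform pool
#'
#' The matrix of fixed-length, peak-aligned spike snippets on which all
#' feature extraction operates. Every row is one spike of
#' `spike_window_length()` samples with its maximum at column
#' `spike_peak_index()` (by convention; set `check_peak = FALSE` for pools
#' imported from containers that were aligned by other software).
#'
#' @param waveforms M x 64 numeric matrix, one spike per row.
#' @param gt_labels integer class per row in `1..L`.
#' @param spike_times integer sample index of each spike peak (optional).
#' @param peak_index column at which every row peaks (1-based; default 20).
#' @param check_peak validate the per-row argmax invariant (default `TRUE`).
#' @return an object of class `waveform_pool`.
#' @export
waveform_pool <- function(waveforms, gt_labels,
                          spike_times = NULL,
                          peak_index = spike_peak_index(),
                          check_peak = TRUE) {
  waveforms <- as.matrix(waveforms)
  gt_labels <- as.integer(gt_labels)
  m <- nrow(waveforms)
  if (length(gt_labels) != m)
    stop("gt_labels length (", length(gt_labels),
         ") does not match pool size (", m, ")")
  if (m > 0 && length(gt_labels) && any(gt_labels < 1L))
    stop("gt_labels must be positive integers (1..L)")
  if (is.null(spike_times)) {
    spike_times <- rep(NA_integer_, m)
  } else {
    spike_times <- as.integer(spike_times)
    if (length(spike_times) != m)
      stop("spike_times length does not match pool size")
  }
  if (check_peak && m > 0) {
    peaks <- apply(waveforms, 1L, which.max)
    if (any(peaks != peak_index))
      stop("waveform rows must peak at column ", peak_index,
           "; offending rows: ",
           paste(utils::head(which(peaks != peak_index), 5L), collapse = ", "))
  }
  structure(list(waveforms = waveforms, peak_index = as.integer(peak_index),
                 gt_labels = gt_labels, spike_times = spike_times),
            class = "waveform_pool")
}

#' @export
print.waveform_pool <- function(x, ...) {
  cat(sprintf("<waveform_pool> M=%d spikes x %d samples, %d classes, peak @ %d\n",
              nrow(x$waveforms), ncol(x$waveforms),
              length(unique(x$gt_labels)), x$peak_index))
  invisible(x)
}

#' Spike window geometry
#'
#' The extraction convention used throughout: 20 samples to the left and 44
#' to the right of the spike peak, a 64-sample window with the peak at
#' sample 20 (1-based).
#' @return an integer scalar.
#' @export
spike_window_length <- function() 64L

#' @rdname spike_window_length
#' @export
spike_peak_index <- function() 20L

#' Construct a feature-set
#'
#' A low-dimensional representation of a waveform pool: either the first
#' three principal-component projections (`kind = "pca"`, d = 3) or the ten
#' Haar wavelet coefficients most deviant from normality
#' (`kind = "wavelet"`, d = 10).
#'
#' @param matrix M x d numeric feature matrix.
#' @param kind `"pca"` or `"wavelet"`.
#' @param gt_labels integer ground-truth class per row.
#' @param label dataset tag (e.g. `"Epca"`, `"Dks"`).
#' @param metadata list of extraction metadata (variance fraction covered,
#'   selected coefficient indices, ...).
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(matrix, kind = c("pca", "wavelet"),
                        gt_labels, label = NA_character_,
                        metadata = list()) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  expected_d <- if (kind == "pca") 3L else 10L
  if (ncol(matrix) != expected_d)
    stop(kind, " feature-sets must have d = ", expected_d,
         " columns, got ", ncol(matrix))
  if (any(!is.finite(matrix)))
    stop("feature matrix contains non-finite entries")
  gt_labels <- as.integer(gt_labels)
  if (length(gt_labels) != nrow(matrix))
    stop("gt_labels length does not match feature matrix rows")
  structure(list(matrix = matrix, kind = kind, label = label,
                 gt_labels = gt_labels, metadata = metadata),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s [%s]: M=%d x d=%d\n",
              ifelse(is.na(x$label), "(unlabelled)", x$label), x$kind,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Construct a partition (clustering outcome)
#'
#' Labels are densely re-indexed to `1..k` on construction, so all
#' downstream scores are invariant to how the producing algorithm happened
#' to number its clusters. A zero-length or all-`NA` label vector yields the
#' empty partition (`k = 0`), the contract for an algorithm that failed to
#' produce any cluster.
#'
#' @param labels integer cluster label per point (any coding), or `NULL`.
#' @param n_points pool size `M`; required for the empty partition so its
#'   length is still known.
#' @return an object of class `spike_partition` with fields `labels`
#'   (length-M, dense `1..k`, or zeros when empty), `k`, and `empty`.
#' @export
spike_partition <- function(labels, n_points = length(labels)) {
  if (is.null(labels) || length(labels) == 0L || all(is.na(labels))) {
    return(structure(list(labels = integer(n_points), k = 0L, empty = TRUE),
                     class = "spike_partition"))
  }
  if (any(is.na(labels)))
    stop("partition labels must be all present or all NA (empty)")
  dense <- match(labels, sort(unique(labels)))
  structure(list(labels = as.integer(dense),
                 k = length(unique(dense)), empty = FALSE),
            class = "spike_partition")
}

#' @export
print.spike_partition <- function(x, ...) {
  if (x$empty) cat(sprintf("<spike_partition> empty (M=%d)\n", length(x$labels)))
  else cat(sprintf("<spike_partition> k=%d clusters over M=%d points\n",
                   x$k, length(x$labels)))
  invisible(x)
}

# Coerce ground truth or a raw label vector to spike_partition.
as_partition <- function(x, n_points = NULL) {
  if (inherits(x, "spike_partition")) return(x)
  spike_partition(x, n_points = if (is.null(n_points)) length(x) else n_points)
}
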