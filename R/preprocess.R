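# Band-pass filtering and windowed, peak-aligned waveform extraction.

#' Zero-phase band-pass filter a recording
#'
#' Removes field potential and out-of-band noise with a Butterworth
#' band-pass applied forward and backward (zero phase), so ground-truth
#' spike times stay aligned with the filtered trace. Defaults (300-3000 Hz,
#' 4th order) follow the conventions of the single-channel benchmark
#' literature. Ground truth passes through unchanged.
#'
#' @param recording a [spike_recording].
#' @param low_hz,high_hz band edges, `0 < low_hz < high_hz < Nyquist`.
#' @param order filter order.
#' @return the filtered [spike_recording].
#' @export
bandpass_filter <- function(recording, low_hz = 300, high_hz = 3000,
                            order = 4L) {
  stopifnot(inherits(recording, "spike_recording"))
  nyq <- recording$sampling_rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("invalid band edges: need 0 < low_hz < high_hz < ", nyq,
         " Hz (got ", low_hz, ", ", high_hz, ")")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  # odd-symmetric edge padding keeps the forward-backward pass's start-up
  # transients out of the trace (three low-edge periods is ample decay room)
  x <- recording$samples
  n <- length(x)
  pad <- min(n - 1L, ceiling(10 * recording$sampling_rate / low_hz))
  padded <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  filtered <- signal::filtfilt(bf, padded)[(pad + 1L):(pad + n)]
  spike_recording(filtered, sampling_rate = recording$sampling_rate,
                  gt_times = recording$gt_times,
                  gt_labels = recording$gt_labels)
}

# Iterate the cut-locate-recut rule to its fixed point: starting from the
# provisional window at t0, re-cut around the window's peak until the peak
# sits at sample 20 of its own window (the value at the peak is strictly
# increasing across moves, so the loop terminates). Returns the converged
# peak sample index, or NA when any window leaves [1, n_samples].
align_peak <- function(trace, t0, peak = "max", max_moves = 50L) {
  left <- spike_peak_index() - 1L
  right <- spike_window_length() - spike_peak_index()
  n_samples <- length(trace)
  p <- t0
  for (mv in seq_len(max_moves)) {
    lo <- p - left
    hi <- p + right
    if (lo < 1L || hi > n_samples) return(NA_integer_)
    win <- trace[lo:hi]
    q <- lo - 1L + if (peak == "max") which.max(win) else which.max(abs(win))
    if (q == p) return(p)
    p <- q
  }
  NA_integer_
}

#' Extract peak-aligned spike waveforms at ground-truth times
#'
#' For each ground-truth spike time a provisional 64-sample window (20
#' samples left, 44 right) is cut, the peak located inside it, and the
#' window re-cut so the peak sits exactly at sample 20 (1-based). Spikes
#' whose re-cut window would leave the trace are dropped with a warning.
#'
#' @param recording a [spike_recording] with ground truth.
#' @param peak `"max"` (most positive sample, the default; matches
#'   positive-peaked benchmark templates) or `"absmax"` for negative-going
#'   data.
#' @return a [waveform_pool]; its `M` may be smaller than the event count
#'   when boundary spikes were dropped (the number is recorded in
#'   `attr(, "n_dropped")`).
#' @export
extract_waveforms <- function(recording, peak = c("max", "absmax")) {
  stopifnot(inherits(recording, "spike_recording"))
  peak <- match.arg(peak)
  if (is.null(recording$gt_times))
    stop("recording carries no ground-truth spike times")
  wlen <- spike_window_length()
  left <- spike_peak_index() - 1L
  right <- wlen - spike_peak_index()
  n <- length(recording$gt_times)
  if (n == 0L)
    return(waveform_pool(matrix(numeric(0), 0L, wlen), integer(0)))
  trace <- recording$samples
  n_samples <- length(trace)
  rows <- matrix(NA_real_, n, wlen)
  times_out <- integer(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- align_peak(trace, recording$gt_times[i], peak = peak)
    if (is.na(p)) next
    rows[i, ] <- trace[(p - left):(p + right)]
    times_out[i] <- p
    keep[i] <- TRUE
  }
  if (!any(keep))
    stop("all ", n, " spikes fell outside the trace bounds")
  if (any(!keep))
    warning(sum(!keep), " of ", n,
            " spikes dropped: window exceeds trace bounds")
  pool <- waveform_pool(rows[keep, , drop = FALSE],
                        gt_labels = recording$gt_labels[keep],
                        spike_times = times_out[keep],
                        check_peak = (peak == "max"))
  attr(pool, "n_dropped") <- sum(!keep)
  pool
}
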