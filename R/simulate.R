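# Synthetic ground-truthed recordings: a small pool of biphasic/triphasic
# spike templates, placed on a single-channel trace at known times with
# additive white Gaussian noise. Emulates the three benchmark regimes:
# low spike-shape similarity ("Easy"), high similarity ("Difficult"), and
# pre-extracted waveform pools ("Real").

gauss_bump <- function(t, mu, sd) exp(-(t - mu)^2 / (2 * sd^2))

# Distinct parametric archetypes for the low-similarity regime; the
# high-similarity regime perturbs one base shape instead.
template_archetype <- function(id, t, jit) {
  j <- function(x, frac) x * (1 + jit[1L] * frac) # deterministic per-call jitter
  switch(((id - 1L) %% 4L) + 1L,
    # narrow biphasic with a fast deep after-hyperpolarization
    gauss_bump(t, 20, j(1.5, 0.06)) -
      j(0.9, 0.08) * gauss_bump(t, j(26, 0.03), 2.5),
    # broad spike with a late shallow trough
    gauss_bump(t, 20, j(5.5, 0.06)) -
      j(0.3, 0.12) * gauss_bump(t, j(44, 0.03), 8),
    # triphasic: pre-spike dip, narrow peak, late positive hump
    -j(0.8, 0.08) * gauss_bump(t, 12, 2.5) + gauss_bump(t, 20, j(1.8, 0.06)) +
      j(0.6, 0.1) * gauss_bump(t, j(32, 0.03), 4),
    # medium-width spike with a slow deep trough
    gauss_bump(t, 20, j(2.2, 0.06)) -
      j(0.85, 0.08) * gauss_bump(t, j(33, 0.03), 6)
  )
}

finish_template <- function(shape) {
  shape <- shape / max(shape) # unit peak amplitude
  shift <- spike_peak_index() - which.max(shape) # enforce peak at sample 20
  n <- length(shape)
  if (shift > 0) shape <- c(rep(shape[1L], shift), shape[seq_len(n - shift)])
  if (shift < 0) shape <- c(shape[(1L - shift):n], rep(shape[n], -shift))
  shape
}

#' Normalized cross-correlation of two templates at lag zero
#'
#' The cosine between two waveforms; the similarity measure used to certify
#' that a template set is in the low- or high-similarity regime.
#'
#' @param a,b numeric waveforms of equal length.
#' @return a scalar in `[-1, 1]`.
#' @export
template_correlation <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

#' Generate a set of spike templates
#'
#' Low similarity draws each class from a distinct parametric archetype
#' (narrow biphasic, broad biphasic, triphasic, fast overshooting); high
#' similarity perturbs a single base shape in width and
#' after-hyperpolarization depth. Each template is 64 samples, unit peak
#' amplitude, peak at sample 20. The generated set is certified against the
#' similarity constraint (pairwise normalized cross-correlation at lag
#' zero) and regenerated with fresh jitter up to `max_tries` times before
#' erroring.
#'
#' @param n_classes number of spike classes (>= 2).
#' @param similarity `"low"` (pairwise correlation below `low_threshold`)
#'   or `"high"` (above `high_threshold`).
#' @param seed integer seed; the same arguments always return the same
#'   templates.
#' @param low_threshold,high_threshold correlation thresholds certifying
#'   the two regimes.
#' @param max_tries regeneration attempts before giving up.
#' @return list of `spike_template` objects (fields `shape`, `class_id`).
#' @export
make_templates <- function(n_classes, similarity = c("low", "high"), seed = 1L,
                           low_threshold = 0.7, high_threshold = 0.9,
                           max_tries = 25L) {
  similarity <- match.arg(similarity)
  stopifnot(n_classes >= 2)
  t <- seq_len(spike_window_length())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    shapes <- if (similarity == "low") {
      lapply(seq_len(n_classes), function(id)
        finish_template(template_archetype(id, t, jit = stats::rnorm(1))))
    } else {
      lapply(seq_len(n_classes), function(id) {
        w <- 2.5 * (1 + stats::rnorm(1, 0, 0.04))
        a <- 0.45 * (1 + stats::rnorm(1, 0, 0.06))
        mu <- 30 + stats::rnorm(1, 0, 0.8)
        finish_template(gauss_bump(t, 20, w) - a * gauss_bump(t, mu, 5))
      })
    }
    cors <- utils::combn(n_classes, 2L, function(ij)
      template_correlation(shapes[[ij[1L]]], shapes[[ij[2L]]]))
    distinct <- all(utils::combn(n_classes, 2L, function(ij)
      any(shapes[[ij[1L]]] != shapes[[ij[2L]]])))
    ok <- distinct && if (similarity == "low")
      max(cors) < low_threshold else min(cors) > high_threshold
    if (ok)
      return(lapply(seq_len(n_classes), function(id)
        structure(list(shape = shapes[[id]], class_id = id),
                  class = "spike_template")))
  }
  stop("could not generate ", n_classes, " templates satisfying the '",
       similarity, "' similarity constraint after ", max_tries, " attempts")
}

# Save/restore .Random.seed so generator calls do not perturb the caller's
# RNG stream beyond their own seeded draws.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-recording generator. `noise_sd` is the
#' standard deviation of the additive white Gaussian noise in units of the
#' (unit) template peak amplitude; the benchmark's lowest noise level is
#' emulated by the 0.05 default. `min_separation` (default 100 samples)
#' keeps consecutive spikes non-overlapping, since the evaluation treats
#' spikes as extracted windows.
#'
#' @param n_classes number of spike classes (3 synthetic / 4 real-like).
#' @param n_spikes number of spike events; classes are balanced up to
#'   divisibility and shuffled.
#' @param similarity `"low"` or `"high"` spike-shape similarity.
#' @param noise_sd noise standard deviation (template peak = 1).
#' @param min_separation minimum gap between consecutive spike peaks,
#'   samples (>= 64, the window length).
#' @param seed integer seed for all randomness in the generator.
#' @param sampling_rate Hz (metadata only; the generator works in samples).
#' @param duration optional trace length in samples; auto-sized when `NULL`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_classes = 3L, n_spikes = 300L,
                       similarity = c("low", "high"), noise_sd = 0.05,
                       min_separation = 100L, seed = 1L,
                       sampling_rate = 24000, duration = NULL) {
  similarity <- match.arg(similarity)
  stopifnot(n_spikes >= n_classes, noise_sd >= 0,
            min_separation >= spike_window_length())
  structure(list(n_classes = as.integer(n_classes),
                 n_spikes = as.integer(n_spikes), similarity = similarity,
                 noise_sd = noise_sd, min_separation = as.integer(min_separation),
                 seed = as.integer(seed), sampling_rate = sampling_rate,
                 duration = duration),
            class = "sim_config")
}

balanced_labels <- function(n_spikes, n_classes) {
  sample(rep_len(seq_len(n_classes), n_spikes))
}

#' Simulate a ground-truthed single-channel recording
#'
#' Places `n_spikes` template instances (classes balanced and shuffled) on a
#' zero baseline at times separated by at least `min_separation` samples,
#' with each spike's peak landing exactly on its ground-truth time, then
#' adds white Gaussian noise. Deterministic per `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [spike_recording] with `gt_times` and `gt_labels`.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  templates <- make_templates(config$n_classes, config$similarity,
                              seed = config$seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  labels <- balanced_labels(config$n_spikes, config$n_classes)
  gaps <- config$min_separation +
    floor(stats::runif(config$n_spikes, 0, config$min_separation / 2))
  times <- spike_window_length() + cumsum(gaps)
  needed <- times[config$n_spikes] + spike_window_length()
  n_samples <- if (is.null(config$duration)) needed else as.integer(config$duration)
  if (n_samples < needed)
    stop("duration ", n_samples, " too short to place ", config$n_spikes,
         " spikes at min_separation ", config$min_separation,
         " (need ", needed, " samples)")
  trace <- numeric(n_samples)
  left <- spike_peak_index() - 1L
  right <- spike_window_length() - spike_peak_index()
  for (i in seq_len(config$n_spikes)) {
    idx <- (times[i] - left):(times[i] + right)
    trace[idx] <- trace[idx] + templates[[labels[i]]]$shape
  }
  if (config$noise_sd > 0)
    trace <- trace + stats::rnorm(n_samples, 0, config$noise_sd)
  spike_recording(trace, sampling_rate = config$sampling_rate,
                  gt_times = times, gt_labels = labels)
}

#' Simulate a pre-extracted waveform pool
#'
#' Bypasses trace assembly: each row is its class template plus i.i.d.
#' Gaussian noise, re-windowed around the noisy peak so the pool satisfies
#' the peak-at-sample-20 alignment invariant exactly (the same re-cut rule
#' as [extract_waveforms()]). Emulates curated containers whose waveforms
#' come pre-extracted.
#'
#' @param config a [sim_config()].
#' @return a [waveform_pool] of `config$n_spikes` rows.
#' @export
simulate_waveform_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  templates <- make_templates(config$n_classes, config$similarity,
                              seed = config$seed)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 2L)
  m <- config$n_spikes
  labels <- balanced_labels(m, config$n_classes)
  wlen <- spike_window_length()
  left <- spike_peak_index() - 1L
  right <- wlen - spike_peak_index()
  pad <- 2L * wlen # room for the peak-alignment re-cut to settle
  rows <- matrix(0, m, wlen)
  for (i in seq_len(m)) {
    clean <- c(numeric(pad), templates[[labels[i]]]$shape, numeric(pad))
    for (try in 1:100) {
      mini <- clean
      if (config$noise_sd > 0)
        mini <- mini + stats::rnorm(length(mini), 0, config$noise_sd)
      p <- align_peak(mini, pad + spike_peak_index())
      if (!is.na(p)) break
    }
    if (is.na(p))
      stop("could not align a noisy waveform after 100 redraws ",
           "(noise_sd = ", config$noise_sd, ")")
    rows[i, ] <- mini[(p - left):(p + right)]
  }
  waveform_pool(rows, gt_labels = labels,
                spike_times = spike_window_length() +
                  cumsum(rep(config$min_separation, m)))
}
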