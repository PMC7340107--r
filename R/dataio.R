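# Reading and writing ground-truthed benchmark containers and score tables.

#' Read a ground-truthed benchmark recording container
#'
#' Reads the MAT v5 dialect used by the public single-channel spike-sorting
#' benchmarks. Two container layouts exist in the wild and both are
#' supported:
#'
#' * **recording** containers hold a 1 x T voltage trace plus ground-truth
#'   spike times (sample indices) and class labels. Variable names vary
#'   between releases, so the reader probes a configurable candidate list
#'   and unwraps one level of cell nesting.
#' * **waveform** containers hold already-extracted spikes: an M x 64
#'   matrix of waveforms and an M x 2 `cluster_class` array (class label,
#'   spike time). These yield a [waveform_pool] directly.
#'
#' @param path path to a `.mat` container.
#' @param mode `"auto"` (default: waveform layout if a waveform matrix is
#'   found, recording otherwise), `"recording"`, or `"waveforms"`.
#' @param data_vars,time_vars,class_vars,waveform_vars candidate variable
#'   names probed, in order, for the trace, spike times, class labels, and
#'   extracted waveform matrix.
#' @param sampling_rate sampling rate in Hz used when the container does not
#'   store one (the benchmark files do not).
#' @return a [spike_recording] (recording mode) or [waveform_pool]
#'   (waveform mode).
#' @export
read_quiroga_dataset <- function(path,
                                 mode = c("auto", "recording", "waveforms"),
                                 data_vars = c("data", "samples"),
                                 time_vars = c("spike_times", "spiketimes", "gt_times"),
                                 class_vars = c("spike_class", "spike_classes", "gt_labels"),
                                 waveform_vars = c("spikes", "waveforms"),
                                 sampling_rate = 24000) {
  mode <- match.arg(mode)
  vars <- read_mat5(path)

  pick <- function(cands) {
    nm <- intersect(cands, names(vars))
    if (length(nm) == 0L) return(NULL)
    unwrap_cell(vars[[nm[1L]]])
  }

  wf <- pick(waveform_vars)
  if (mode == "waveforms" || (mode == "auto" && !is.null(wf))) {
    if (is.null(wf))
      stop("unrecognized container layout: no waveform matrix among ",
           "variables found (", paste(names(vars), collapse = ", "), ")")
    cc <- unwrap_cell(vars[["cluster_class"]])
    if (is.null(cc))
      stop("unrecognized container layout: waveform container lacks ",
           "'cluster_class'; variables found (",
           paste(names(vars), collapse = ", "), ")")
    labels_raw <- as.integer(round(cc[, 1L]))
    # stored class 0 = unsorted in curated real containers; re-index densely
    labels <- match(labels_raw, sort(unique(labels_raw)))
    times <- if (ncol(cc) >= 2L)
      as.integer(round(cc[, 2L] / 1000 * sampling_rate)) else NULL
    return(waveform_pool(wf, gt_labels = labels, spike_times = times,
                         check_peak = FALSE))
  }

  trace <- pick(data_vars)
  if (is.null(trace))
    stop("unrecognized container layout: no voltage trace among ",
         "variables found (", paste(names(vars), collapse = ", "), ")")
  times <- pick(time_vars)
  labels <- pick(class_vars)
  if (is.null(times) != is.null(labels))
    stop("unrecognized container layout: spike times and classes must both ",
         "be present or both absent; variables found (",
         paste(names(vars), collapse = ", "), ")")
  sr <- unwrap_cell(vars[["sampling_rate"]])
  if (!is.null(sr)) sampling_rate <- as.numeric(sr)[1L]
  times <- if (!is.null(times)) as.numeric(times) else NULL
  if (!is.null(times) && is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stop("ground-truth spike times are not strictly increasing")
  spike_recording(samples = as.numeric(trace),
                  sampling_rate = sampling_rate,
                  gt_times = times,
                  gt_labels = if (!is.null(labels)) as.numeric(labels) else NULL)
}

# Benchmark containers sometimes wrap vectors in one level of cell array.
unwrap_cell <- function(x) {
  if (is.list(x)) {
    if (length(x) == 1L) return(unwrap_cell(x[[1L]]))
    return(unlist(lapply(x, unwrap_cell), use.names = FALSE))
  }
  x
}

#' Write a recording in the benchmark container dialect
#'
#' Emits a MAT v5 file that [read_quiroga_dataset()] reads back losslessly:
#' `data` (1 x T trace), `sampling_rate`, and — when ground truth is present
#' — `spike_times` and `spike_class`. Lets the simulator produce fixtures in
#' the same dialect the reader consumes.
#'
#' @param recording a [spike_recording].
#' @param path output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_quiroga_dataset <- function(recording, path) {
  stopifnot(inherits(recording, "spike_recording"))
  vars <- list(data = matrix(recording$samples, nrow = 1L),
               sampling_rate = recording$sampling_rate)
  if (!is.null(recording$gt_times)) {
    vars$spike_times <- as.numeric(recording$gt_times)
    vars$spike_class <- as.numeric(recording$gt_labels)
  }
  write_mat5(vars, path)
  invisible(path)
}

#' Persist and reload an evaluation score table
#'
#' A score table (see [evaluate_all()]) is written as one CSV per metric
#' family — external indices, internal indices (raw and normalized), and
#' per-algorithm consistency/category scores — plus a JSON summary with run
#' metadata so results are diffable and bit-reproducible.
#'
#' @param table a `score_table` as returned by [evaluate_all()].
#' @param dir output directory (created if needed).
#' @return `dir` (write) / a `score_table` (read).
#' @export
write_score_table <- function(table, dir) {
  stopifnot(inherits(table, "score_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table$external, file.path(dir, "external.csv"),
                   row.names = FALSE)
  utils::write.csv(table$internal, file.path(dir, "internal.csv"),
                   row.names = FALSE)
  utils::write.csv(table$nii_variance, file.path(dir, "nii_variance.csv"),
                   row.names = FALSE)
  cons <- table$consistency
  cons$category <- as.character(cons$category)
  utils::write.csv(cons, file.path(dir, "consistency.csv"),
                   row.names = FALSE)
  if (!is.null(table$confusion)) {
    cdir <- file.path(dir, "confusion")
    dir.create(cdir, showWarnings = FALSE)
    for (fname in names(table$confusion))
      for (a in names(table$confusion[[fname]]))
        utils::write.csv(table$confusion[[fname]][[a]]$counts,
                         file.path(cdir, paste0(fname, "_", a, ".csv")),
                         row.names = FALSE)
  }
  jsonlite::write_json(table$meta, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(dir) {
  files <- file.path(dir, c("external.csv", "internal.csv",
                            "nii_variance.csv", "consistency.csv",
                            "summary.json"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("score-table schema mismatch: missing ",
         paste(basename(missing), collapse = ", "), " in ", dir)
  cons <- utils::read.csv(files[4L], stringsAsFactors = FALSE)
  cons$category <- factor(cons$category,
                          levels = c("ideal", "most-compatible", "compatible",
                                     "average", "least-compatible",
                                     "non-compatible"))
  structure(list(
    external = utils::read.csv(files[1L], stringsAsFactors = FALSE),
    internal = utils::read.csv(files[2L], stringsAsFactors = FALSE),
    nii_variance = utils::read.csv(files[3L], stringsAsFactors = FALSE),
    consistency = cons,
    confusion = NULL,
    meta = jsonlite::read_json(files[5L], simplifyVector = TRUE)
  ), class = "score_table")
}
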