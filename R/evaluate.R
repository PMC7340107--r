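# Full evaluation grid: every algorithm x feature-set scored with external
# indices, accuracy, raw + normalized internal indices, then consolidated
# into per-algorithm consistency scores and compatibility categories.

#' Evaluate a set of algorithms over a set of feature-sets
#'
#' Runs every algorithm on every feature-set (supervised algorithms receive
#' `n` partitions) alongside the `"ground-truth"` pseudo-algorithm whose
#' partition is the ground-truth labeling itself, and computes the full
#' scoring stack:
#'
#' * external indices (Rand, Jaccard) and best-match confusion-matrix
#'   accuracy per algorithm x feature-set;
#' * raw internal indices (Davies-Bouldin, Ball-Hall, Trace-W), normalized
#'   per (criterion, feature-set) against the ground-truth reference
#'   ([normalize_internal()]);
#' * the inverted-RMSE consistency score per algorithm across all
#'   feature-sets, computed from Rand only by default (Jaccard fails to
#'   produce an index for degenerate partitions; a config flag adds it);
#' * compatibility categories ([categorize()]) and the NII-variance
#'   index-consistency diagnostic ([index_consistency()]).
#'
#' Individual algorithm failures degrade to the empty partition (external
#' indices 0, internal indices flagged `NA`) and never abort the grid.
#' Undefined internal cells — empty or single-cluster partitions for
#' Davies-Bouldin, coincident centroids — are flagged `NA`, not imputed.
#'
#' @param feature_sets named list of [feature_set] objects, each carrying
#'   ground truth.
#' @param specs list of [algorithm_spec] objects (or algorithm names, which
#'   are instantiated with `seed`).
#' @param n partition count handed to supervised algorithms (3 for the
#'   synthetic benchmark regime, 4 for the real one).
#' @param rmse_indices external criteria entering the consistency RMSE
#'   (default `"rand"`).
#' @param breaks optional fixed category thresholds (see [categorize()]).
#' @param seed seed used when `specs` are given as names.
#' @return a `score_table`: list with data frames `external` (long:
#'   algorithm, featureset, criterion, value, flagged), `internal` (long:
#'   raw, normalized, reference, flagged), `nii_variance` (per algorithm x
#'   feature-set), `consistency` (per algorithm: rmse, inverted,
#'   n_feature_sets, nii_variance, category), plus `confusion` (nested list
#'   of confusion matrices) and `meta`.
#' @export
evaluate_all <- function(feature_sets, specs, n = 3L,
                         rmse_indices = "rand", breaks = NULL, seed = 1L) {
  stopifnot(length(feature_sets) > 0)
  if (is.null(names(feature_sets)) || any(!nzchar(names(feature_sets))))
    names(feature_sets) <- paste0("fs", seq_along(feature_sets))
  specs <- lapply(specs, function(s)
    if (inherits(s, "algorithm_spec")) s else algorithm_spec(s, seed = seed))
  alg_names <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(alg_names))
    stop("duplicate algorithm names in specs: ",
         paste(unique(alg_names[duplicated(alg_names)]), collapse = ", "))
  all_algs <- c("ground-truth", alg_names)

  ext <- int <- niiv <- list()
  confusion <- list()

  for (fname in names(feature_sets)) {
    fs <- feature_sets[[fname]]
    gt <- fs$gt_labels
    partitions <- list("ground-truth" = spike_partition(gt))
    for (s in specs) {
      partitions[[s$name]] <- if (s$mode == "supervised")
        run_supervised(s, fs, n) else run_unsupervised(s, fs)
    }
    confusion[[fname]] <- list()

    raw_int <- matrix(NA_real_, length(all_algs), 3L,
                      dimnames = list(all_algs, c("DB", "BH", "TrW")))
    for (a in all_algs) {
      p <- partitions[[a]]
      cm <- match_confusion_matrix(gt, p)
      confusion[[fname]][[a]] <- cm
      jac <- jaccard_index(gt, p)
      ext[[length(ext) + 1L]] <- data.frame(
        algorithm = a, featureset = fname,
        criterion = c("rand", "jaccard", "accuracy"),
        value = c(rand_index(gt, p), as.numeric(jac), accuracy(cm)),
        flagged = c(FALSE, isTRUE(attr(jac, "no_index")), FALSE))
      if (!p$empty) {
        raw_int[a, "BH"] <- ball_hall(fs, p)
        raw_int[a, "TrW"] <- trace_w(fs, p)
        if (p$k >= 2) {
          db <- suppressWarnings(davies_bouldin(fs, p))
          raw_int[a, "DB"] <- if (is.nan(db)) NA_real_ else db
        }
      }
    }

    nii <- raw_int
    for (crit in colnames(raw_int)) {
      vals <- raw_int[, crit]
      r <- raw_int["ground-truth", crit]
      ok <- !is.na(vals)
      if (is.na(r)) { nii[, crit] <- NA_real_; next }
      nii[ok, crit] <- normalize_internal(vals[ok], r)
    }
    for (a in all_algs) {
      int[[length(int) + 1L]] <- data.frame(
        algorithm = a, featureset = fname,
        criterion = colnames(raw_int),
        raw = raw_int[a, ], normalized = nii[a, ],
        reference = raw_int["ground-truth", ],
        flagged = is.na(raw_int[a, ]))
      niiv[[length(niiv) + 1L]] <- data.frame(
        algorithm = a, featureset = fname,
        nii_variance = index_consistency(nii[a, c("BH", "TrW", "DB")]))
    }
  }

  external <- do.call(rbind, ext)
  internal <- do.call(rbind, int)
  rownames(internal) <- NULL
  nii_variance <- do.call(rbind, niiv)

  consistency <- do.call(rbind, lapply(all_algs, function(a) {
    e <- external$value[external$algorithm == a &
                          external$criterion %in% rmse_indices]
    ir <- inverted_rmse(e)
    data.frame(algorithm = a, rmse = ir$rmse, inverted = ir$inverted,
               n_feature_sets = length(feature_sets),
               nii_variance = mean(
                 nii_variance$nii_variance[nii_variance$algorithm == a],
                 na.rm = TRUE))
  }))
  consistency <- categorize(consistency, breaks = breaks)

  structure(list(external = external, internal = internal,
                 nii_variance = nii_variance, consistency = consistency,
                 confusion = confusion,
                 meta = list(
                   algorithms = all_algs,
                   feature_sets = names(feature_sets),
                   n_partitions = n,
                   rmse_indices = rmse_indices,
                   n_feature_sets = length(feature_sets),
                   seeds = stats::setNames(
                     lapply(specs, function(s) s$seed), alg_names))),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d algorithms x %d feature-sets\n",
              length(x$meta$algorithms), x$meta$n_feature_sets))
  acc <- x$external[x$external$criterion == "accuracy", ]
  wide <- stats::reshape(acc[, c("algorithm", "featureset", "value")],
                         idvar = "algorithm", timevar = "featureset",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "acc.", names(wide))
  print(merge(wide, x$consistency[, c("algorithm", "inverted", "category")],
              by = "algorithm"), digits = 4)
  invisible(x)
}
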