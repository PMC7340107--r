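# Uniform supervised/unsupervised clustering contracts over a registry of
# algorithm adapters. Supervised algorithms receive the desired partition
# count n; unsupervised algorithms determine cluster structure themselves.
# Euclidean distance throughout. Adapter failures degrade to the empty
# partition (never abort an evaluation run).

.registry <- new.env(parent = emptyenv())

#' Algorithm specification
#'
#' Names a registered clustering algorithm, its contract mode, adapter
#' parameters, and the seed handed to the adapter (all stochastic adapters
#' are explicitly seeded, so runs are reproducible).
#'
#' @param name registered algorithm name (see [registry()]).
#' @param params named list of adapter parameter overrides.
#' @param seed integer seed.
#' @return an `algorithm_spec`.
#' @export
algorithm_spec <- function(name, params = list(), seed = 1L) {
  entry <- registry_entry(name)
  structure(list(name = name, mode = entry$mode,
                 params = utils::modifyList(entry$defaults, params),
                 seed = as.integer(seed)),
            class = "algorithm_spec")
}

#' Register a clustering algorithm adapter
#'
#' Extends the registry. An adapter is a function
#' `function(x, n, params)` returning an integer label per row of `x`
#' (0 = noise; noise points are mapped to a dedicated extra cluster so
#' every spike keeps a label) or `NULL`/error for failure. Unsupervised
#' adapters ignore `n`.
#'
#' @param name algorithm name.
#' @param mode `"supervised"` or `"unsupervised"`.
#' @param fn the adapter function.
#' @param defaults named list of default parameters.
#' @export
register_algorithm <- function(name, mode = c("supervised", "unsupervised"),
                               fn, defaults = list()) {
  mode <- match.arg(mode)
  assign(name, list(mode = mode, fn = fn, defaults = defaults),
         envir = .registry)
  invisible(name)
}

registry_entry <- function(name) {
  if (!exists(name, envir = .registry, inherits = FALSE))
    stop("unknown algorithm '", name, "'; available: ",
         paste(sort(ls(.registry)), collapse = ", "))
  get(name, envir = .registry)
}

#' The algorithm registry
#'
#' One [algorithm_spec] per registered adapter. The built-in set wraps
#' established implementations: k-means, k-medoids (PAM), Ward
#' agglomerative, spectral, EM Gaussian mixture and fuzzy c-means in
#' supervised mode; BIC-selected Gaussian mixture, DBSCAN and mean-shift in
#' unsupervised mode. Further algorithms can be added with
#' [register_algorithm()].
#'
#' @param seed seed given to every spec.
#' @return named list of [algorithm_spec] objects.
#' @export
registry <- function(seed = 1L) {
  nms <- sort(ls(.registry))
  stats::setNames(lapply(nms, algorithm_spec, seed = seed), nms)
}

# Map noise label 0 to a dedicated extra cluster; all-noise -> empty.
resolve_noise <- function(labels) {
  if (is.null(labels) || length(labels) == 0L) return(NULL)
  if (all(labels == 0L)) return(NULL)
  if (any(labels == 0L)) labels[labels == 0L] <- max(labels) + 1L
  labels
}

run_adapter <- function(spec, fs, n) {
  x <- fs$matrix
  labels <- tryCatch({
    set.seed(spec$seed)
    entry <- registry_entry(spec$name)
    entry$fn(x, n, spec$params)
  }, error = function(e) {
    warning("algorithm '", spec$name, "' failed (",
            conditionMessage(e), "); returning the empty partition",
            call. = FALSE)
    NULL
  })
  spike_partition(resolve_noise(labels), n_points = nrow(x))
}

#' Run a supervised clustering algorithm
#'
#' The supervised contract: the algorithm receives the feature matrix and
#' the desired partition count `n` and returns an integer label vector with
#' at most `n` distinct labels. `n = 1` trivially yields the single-cluster
#' partition. Adapter failures return the empty partition with a warning.
#'
#' @param spec an [algorithm_spec] with supervised mode.
#' @param fs a [feature_set].
#' @param n desired number of partitions (3 for the synthetic benchmark
#'   datasets, 4 for the real one).
#' @return a [spike_partition].
#' @export
run_supervised <- function(spec, fs, n) {
  stopifnot(inherits(spec, "algorithm_spec"), inherits(fs, "feature_set"))
  if (spec$mode != "supervised")
    stop("algorithm '", spec$name, "' is not supervised")
  if (n < 1) stop("n must be >= 1")
  if (n == 1) return(spike_partition(rep(1L, nrow(fs$matrix))))
  run_adapter(spec, fs, as.integer(n))
}

#' Run an unsupervised clustering algorithm
#'
#' The unsupervised contract: the algorithm receives only the feature
#' matrix and determines the cluster structure itself — possibly the empty
#' partition (no clusters found), a single cluster, or far more clusters
#' than classes. Downstream scoring handles all three regimes.
#'
#' @param spec an [algorithm_spec] with unsupervised mode.
#' @param fs a [feature_set].
#' @return a [spike_partition].
#' @export
run_unsupervised <- function(spec, fs) {
  stopifnot(inherits(spec, "algorithm_spec"), inherits(fs, "feature_set"))
  if (spec$mode != "unsupervised")
    stop("algorithm '", spec$name, "' is not unsupervised")
  run_adapter(spec, fs, NULL)
}

# ---- reference implementations (no maintained package in the stack) ----

# Plain DBSCAN on a full distance matrix; 0 = noise.
dbscan_labels <- function(x, eps, min_pts) {
  m <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nb <- lapply(seq_len(m), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- integer(m)
  cl <- 0L
  for (i in seq_len(m)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier)) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

# Mean-shift with a flat kernel: ascend each point to the mean of its
# bandwidth neighborhood; merge modes closer than bandwidth / 2.
meanshift_labels <- function(x, bandwidth, max_iter = 100L, tol = 1e-5) {
  m <- nrow(x)
  modes <- x
  for (i in seq_len(m)) {
    p <- x[i, ]
    for (it in seq_len(max_iter)) {
      d2 <- colSums((t(x) - p)^2)
      within <- d2 <= bandwidth^2
      new_p <- colMeans(x[within, , drop = FALSE])
      if (sqrt(sum((new_p - p)^2)) < tol) { p <- new_p; break }
      p <- new_p
    }
    modes[i, ] <- p
  }
  labels <- integer(m)
  centers <- NULL
  for (i in seq_len(m)) {
    if (!is.null(centers)) {
      d <- sqrt(colSums((t(centers) - modes[i, ])^2))
      hit <- which(d < bandwidth / 2)
    } else hit <- integer(0)
    if (length(hit)) labels[i] <- hit[1L]
    else {
      centers <- rbind(centers, modes[i, ])
      labels[i] <- nrow(centers)
    }
  }
  labels
}

# Scale-aware default radii for the density/mode-seeking adapters.
default_eps <- function(x, k = 4L) {
  d <- as.matrix(stats::dist(x))
  kth <- apply(d, 1L, function(r) sort(r)[k + 1L])
  stats::median(kth) * 1.5
}

register_builtin_algorithms <- function() {
  register_algorithm("kmeans", "supervised",
    function(x, n, p) stats::kmeans(x, centers = n, nstart = p$nstart,
                                    iter.max = 300L)$cluster,
    defaults = list(nstart = 10L))
  register_algorithm("kmedoids", "supervised",
    function(x, n, p) cluster::pam(x, k = n, cluster.only = TRUE))
  register_algorithm("agglomerative", "supervised",
    function(x, n, p) stats::cutree(stats::hclust(stats::dist(x),
                                                  method = p$linkage), k = n),
    defaults = list(linkage = "ward.D2"))
  register_algorithm("spectral", "supervised",
    function(x, n, p) as.integer(kernlab::specc(as.matrix(x), centers = n)))
  register_algorithm("gmm_em", "supervised",
    function(x, n, p) mclust::Mclust(x, G = n, verbose = FALSE)$classification)
  register_algorithm("fuzzy_cmeans", "supervised",
    function(x, n, p) e1071::cmeans(x, centers = n, iter.max = 200L)$cluster)
  register_algorithm("gmm_bic", "unsupervised",
    function(x, n, p) mclust::Mclust(x, G = seq_len(p$max_g),
                                     verbose = FALSE)$classification,
    defaults = list(max_g = 9L))
  register_algorithm("dbscan", "unsupervised",
    function(x, n, p) {
      eps <- if (is.null(p$eps)) default_eps(x) else p$eps
      dbscan_labels(x, eps = eps, min_pts = p$min_pts)
    },
    defaults = list(eps = NULL, min_pts = 5L))
  register_algorithm("meanshift", "unsupervised",
    function(x, n, p) {
      bw <- if (is.null(p$bandwidth))
        stats::quantile(stats::dist(x), 0.2, names = FALSE) else p$bandwidth
      meanshift_labels(x, bandwidth = bw)
    },
    defaults = list(bandwidth = NULL))
}
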