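Package: spikebench
Title: Compatibility Evaluation of Clustering Algorithms for Spike Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking toolkit for extracellular spike sorting. Builds
    ground-truthed waveform pools from simulated or stored single-channel
    recordings, extracts the two canonical feature representations (three
    principal components; ten Haar wavelet coefficients selected by deviation
    from normality), runs a registry of clustering algorithms under uniform
    supervised/unsupervised contracts, and scores every algorithm with a
    best-match confusion matrix, accuracy, external indices (Rand, Jaccard),
    internal indices (Davies-Bouldin, Ball-Hall, Trace-W), ground-truth
    referenced normalized internal indices, an inverted root-mean-squared-error
    consistency score across feature-sets, and six-level compatibility
    categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    mclust,
    e1071,
    kernlab,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
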