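---
title: "Evaluating clustering algorithms for spike sorting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating clustering algorithms for spike sorting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikebench)
```

## The problem

Extracellular electrodes record the superimposed action potentials of
several nearby neurons. Spike sorting recovers the single-neuron spike
trains by clustering the detected waveforms in a low-dimensional feature
space. Dozens of general-purpose clustering algorithms have been applied to
this step, and they disagree: some need the cluster count up front, some
find it themselves, some fail outright on spike data. `spikebench`
quantifies that disagreement on ground-truthed recordings — data where the
true spike times and classes are known — so an algorithm's *compatibility*
with spike sorting can be measured rather than asserted.

The package evaluates clusterings, it does not detect spikes: extraction
starts from the known ground-truth event times, which isolates the
clustering stage from detection errors.

## The pipeline

**Waveform pools.** A recording is band-pass filtered (zero-phase
Butterworth, 300–3000 Hz, 4th order by default — the conventions of the
single-channel benchmark literature; the band and order are arguments of
`bandpass_filter()`). At each ground-truth time a 64-sample window is cut
— 20 samples left of the peak, 44 right — and re-cut around its maximum
until the peak sits exactly at sample 20. The re-cut is iterated to a
fixed point: at realistic noise levels a single re-cut can land a window
whose maximum lies elsewhere, and the iteration (each move strictly
increases the peak value, so it terminates) is what guarantees the
alignment invariant that every downstream stage assumes. Windows that
would leave the trace are dropped and counted, never padded, since padding
would distort features. Whether the "peak" is the maximum or the
maximum-absolute sample is a flag (`peak = "max"` by default; the built-in
templates and the public benchmark shapes are positive-peaked).

**Feature-sets.** Two canonical representations are built per pool:

* `pca_features()` — the waveforms are mean-centered and projected onto
  the three components of largest variance. Three components is the
  binding rule; the fraction of variance they cover is reported in
  metadata (curated benchmark pools reach about 95%) but never enforced,
  because arbitrary pools cannot guarantee both.
* `wavelet_features()` — each waveform is decomposed with an orthonormal
  5-level Haar DWT and each of the 64 coefficient positions is scored
  across the pool by a Lilliefors-style Kolmogorov–Smirnov statistic
  (empirical CDF of the standardized sample against the standard normal).
  Coefficients that deviate most from normality are multimodal across
  spike classes, so the ten highest-scoring coefficients are kept, raw
  (no standardization — only the ranking uses the statistic). Ties break
  toward the lower coefficient index for determinism; a pool where every
  coefficient scores zero falls back to the first ten indices with a
  warning.

`knn_graph()` exports the K = 11 nearest-neighbor directed graph with
Euclidean edge weights as a plain-text edge list, the input dialect of
graph-based clusterers; consumers needing an undirected graph symmetrize
it explicitly.

**Clustering contracts.** Every algorithm runs through one of two uniform
contracts: supervised — the adapter receives the feature matrix and the
desired partition count `n` (3 for the synthetic benchmark regime, 4 for
the real one) — or unsupervised, which receives features only and may
return anything from zero clusters to far more than the class count. All
label vectors are densely re-indexed to `1..k` on construction, so scores
cannot depend on an algorithm's label numbering. Noise points from
density-based algorithms keep a label in a dedicated extra cluster
(accuracy's denominator is the total spike count, so dropping them would
silently inflate scores); a partition that is *all* noise is the empty
partition. Adapter errors degrade to the empty partition with a warning
and never abort an evaluation grid. Fuzzy memberships are hardened by
arg-max. The built-in registry wraps established implementations (k-means
with 10 restarts, PAM k-medoids, Ward agglomerative, spectral, EM Gaussian
mixture, fuzzy c-means; BIC-selected Gaussian mixture, DBSCAN and
mean-shift unsupervised) and is extensible with `register_algorithm()` for
algorithms without a maintained implementation in this stack.

## Scoring

**Confusion matrix and accuracy.** Ground-truth classes are matched
one-to-one to clusters by descending overlap count, greedily, with
deterministic tie-breaks (lower class label, then lower cluster label).
Greedy was chosen over exhaustive optimal assignment for transparency and
auditability; the optimal mode exists (`method = "optimal"`) and the test
suite verifies greedy never exceeds it. Matched clusters occupy the
diagonal; spikes of class *l* inside a different matched cluster fill that
row's off-diagonal cell; spikes in unmatched clusters cannot fit an
L × L table and are counted separately as discarded, so
`sum(counts) + discarded` always equals the spike count. Accuracy is
`100 * sum(diag) / M` with M the *total* spike count.

**External indices.** Pair-counting Rand and Jaccard against the
ground-truth labeling, computed from the contingency table. An empty
partition scores Rand 0; Jaccard with an empty positive set is reported as
0 *flagged* "no index produced", which mirrors how degenerate outcomes are
reported in practice rather than pretending a measured zero.

**Internal indices.** Ball–Hall (mean over clusters of within-cluster mean
squared distance to the barycentre), Trace-W (total within-cluster squared
scatter — deliberately unnormalized, so it grows with M), and
Davies–Bouldin. Single-cluster partitions keep BH/TrW (global scatter) but
flag DB, whose formula needs two clusters; coincident centroids also flag
the cell. Flagged cells stay `NA` — never imputed.

**Normalization (NII).** Raw internal indices live on incomparable scales,
so for each (criterion, feature-set) pair every algorithm's value *i* is
mapped to `1 - |r - i| / (max(I) - min(I))` with *r* the ground-truth
partition's value. The reference is included in the range set — the
source procedure leaves open whether the ground truth lies inside the
observed range, and including it is the choice that keeps every normalized
score in [0, 1] with the ground truth at exactly 1.

**Consistency and categories.** An algorithm's external indices across all
N feature-sets are collapsed into `1 - sqrt(sum((1 - e_f)^2) / N)` — an
inverted root-mean-squared error against the ideal score 1 (the square
root is applied as the name demands). Rand alone feeds this score by
default because Jaccard fails to produce an index for degenerate
partitions; `rmse_indices = c("rand", "jaccard")` adds it. Algorithms are
ranked by the inverted score and binned into five categories below
"ideal" (most-compatible, compatible, average, least-compatible,
non-compatible). The bins are rank quintiles by default because no fixed
thresholds are canonical; `breaks` substitutes fixed cut points. Finally,
the population variance of the three NII values per algorithm-featureset
pair is the *index-consistency* diagnostic: high variance — the internal
indices disagreeing with each other — flags an incompatible algorithm
even when no ground truth is available.

A caution the degenerate cases make concrete: a single all-encompassing
cluster over three balanced classes still scores Rand ≈ 0.33 and accuracy
≈ 33.3% (one class sits on the diagonal), and raw internal indices of such
partitions can sit deceptively close to the ground truth's. The
index-consistency variance and the confusion matrix are the guards against
reading those numbers as success.

## The simulator

`simulate_recording()` and `simulate_waveform_pool()` make every stage
testable without downloads. Templates are smooth 64-sample
difference-of-Gaussians/triphasic shapes with unit peak at sample 20. The
*low-similarity* regime draws each class from a distinct archetype (narrow
biphasic, broad biphasic, triphasic, fast overshooting); *high similarity*
perturbs one base shape in width and after-hyperpolarization depth. Each
generated set is certified against its regime — pairwise normalized
cross-correlation at lag 0 below 0.7 (low) or above 0.9 (high) — and
regenerated with fresh jitter when the constraint fails, erroring after
bounded retries. Spikes are placed with a minimum separation of 100
samples (≥ the 64-sample window, so spikes never overlap — the evaluation
treats spikes as extracted windows, and overlap modelling would confound
the clustering comparison), classes balanced and shuffled, plus additive
white Gaussian noise whose standard deviation is expressed in units of the
template peak; 0.05 emulates the quietest benchmark regime. Everything is
deterministic per seed.

What the simulator does *not* emulate: bursting amplitude attenuation,
electrode drift, correlated or non-Gaussian noise, overlapping spikes, and
real template shapes. Passing tests on simulated data therefore
demonstrate the correctness of the machinery and the qualitative
low/high-similarity ordering, not sorting performance on any particular
tissue.

## Numerical choices and degenerate inputs

* Zero-noise pools collapse each class to a point: a 3-class pool is rank
  2 after centering, so `pca_features()` refuses it (the error names the
  achieved rank) while the wavelet path handles it.
* The KS statistic of a zero-variance coefficient is defined as 0 with a
  warning — the coefficient carries no information.
* The second-difference partition-count selection rules
  (`select_partition()`) are defined at interior positions; a constant
  series returns the smallest count under every rule.
* Problem sizes in the test suite are scaled to keep the full pipeline
  exercised in seconds: pools of 40–600 spikes for unit tests, 300 spikes
  across 10 seeds for parameter recovery, and 3,000–3,522 events for the
  balanced-degenerate and container-scale checks. These sizes were chosen
  so that the statistical assertions have comfortable margins at the
  stated noise levels.

## Reading and writing containers

`read_quiroga_dataset()` understands the MAT v5 dialect of the public
single-channel benchmarks: a 1 × T trace with `spike_times` /
`spike_class` vectors (names configurable, one level of cell nesting
unwrapped, sampling rate defaulting to 24 kHz when absent), or a
waveform container holding already-extracted spikes plus a
`cluster_class` array, which yields a pool directly. The MAT codec is
implemented in-package (double/int arrays, compressed elements on read)
and `write_quiroga_dataset()` lets the simulator emit fixtures in the same
dialect the reader consumes — the round trip is exercised in the tests.
Score tables persist as diffable CSV plus a JSON summary; runs are
reproduced byte-for-byte from a config and seed.

## Known limitations

Only a representative subset of clustering algorithms ships as built-in
adapters; the others named in the spike-sorting literature (graph-based
protein-interaction clusterers, SPC, Chameleon, CURE, ROCK, CAST,
ISO-SPLIT, Klustakwik, BIRCH, OPTICS, affinity propagation, variational
mixtures) are reachable through `register_algorithm()` but not bundled.
The framework's claims are about the *evaluation machinery*; conclusions
about any specific algorithm transfer only as far as its adapter matches
the implementation a user would deploy. Single-channel pools only — no
probe geometry, no multi-channel templates.
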