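---
title: "Methods: similarity networks for archaeological trait assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity networks for archaeological trait assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asnet)
```

## The model

An archaeological similarity network (ASN) treats each dated occupation as
a node and encodes cultural resemblance between occupations as weighted
edges. The underlying premise — greater resemblance between assemblages
reflects stronger past interaction or transmission — is an interpretive
assumption, not something the package can test; what the package does is
make every quantitative step of the construction explicit, reproducible
and validated.

The pipeline is: trait table → pairwise similarity → connectivity
threshold → weighted network → descriptive statistics →
isolation-by-distance tests, optionally repeated on consecutive
time-sequence subsets.

### Similarity indices

Both indices live on [0, 1], where 1 means indistinguishable assemblages.

* **Brainerd-Robinson** (count data). With within-assemblage proportions
  `p_a = a / sum(a)`, `BR(a, b) = 1 − ½ Σ_k |p_ak − p_bk|`. This is the
  classical 0–200 statistic divided by 200. Working on proportions makes
  the index invariant to assemblage size, which matters because sherd
  counts vary over orders of magnitude between occupations; it also means
  an occupation with a zero total is undefined and rejected at
  validation. Counts are required to be non-negative integers with
  positive row sums.
* **Jaccard** (presence/absence data). `|A ∩ B| / |A ∪ B|` over the trait
  sets present in either occupation. Presence coding is preferable for
  small finds such as beads, whose recovery counts are sensitive to field
  methods. A pair of empty assemblages has an undefined Jaccard value and
  raises an error rather than silently returning 0 or 1; validation
  already refuses occupations with no recorded traits, so this arises
  only with hand-built matrices.

The *cultural distance* used by the Mantel tests is `1 − S`. Any monotone
decreasing transform would give the same permutation test up to sign; the
complement is the simplest, keeps the [0, 1] scale, and makes a positive
Mantel r read as "less similar when farther apart".

### Thresholding

Retaining every positive-weight edge gives an unreadable near-complete
graph, so the network keeps only edges at or above a threshold. The
selection rule is connectivity-preserving: the threshold is the **largest
observed edge weight t such that the graph with edges {w ≥ t} still has a
connected component covering at least n − k nodes**, with `max_outliers =
k` tolerated dropouts (default 0). For k = 0 this equals the bottleneck
(minimum) edge weight of a maximum spanning tree, which is how the test
suite cross-checks it. Ties at the threshold are kept (the rule is `≥`),
edge weights are never rescaled after cutting, and the resolved threshold
is stored on the graph and in the pipeline provenance so that a published
cut can be imposed verbatim in reproduction runs. The number of tolerated
outliers in any given published analysis is rarely stated, which is why
`max_outliers` is an explicit parameter rather than a heuristic.

### Descriptive statistics

* **Density** counts isolated nodes in the denominator: `2E / (n(n−1))`.
* **Cluster coefficient**: global transitivity (3 × triangles / connected
  triples) on the binarized threshold graph is the default, matching the
  convention of the igraph-based ASN tutorials this workflow descends
  from; the average-local variant (isolates and degree-1 nodes
  contributing 0) is available via `variant = "avg_local"`. Published
  reports often name the metric without a formula, so both are exposed
  and the choice is recorded in the statistics report.
* **Centralities.** Strength is the sum of incident similarity weights.
  Eigenvector centrality is the leading eigenvector of the weighted
  adjacency matrix, computed by a full symmetric eigendecomposition
  (deterministic, no iterative-start jitter) and scaled so the **mean
  score is 1**; published node tables with maxima around 1.8–2.3 on
  networks of 30–50 nodes are consistent with mean-1 scaling and not with
  max-1 scaling. Betweenness is computed on the binarized graph with
  fractional splitting among equal-length paths: observed published
  scores are integers or thirds/sixths, which weighted-distance
  betweenness would essentially never produce.
* **Freeman centralization** is `Σ(c_max − c_i)` divided by a theoretical
  maximum: `(n−1)(n−2)` for strength (attained by a unit-weight star when
  weights are bounded by 1), `(n−1)²(n−2)/2` for betweenness, and `n−1`
  for eigenvector scores rescaled to max 1. One caveat: some published
  graph-level betweenness centralizations are reported around 1e−7,
  orders of magnitude below any documented normalization we are aware of;
  this package reports the Freeman value and prints the formula
  convention with the report rather than reverse-engineering an
  undocumented constant.
* **Interval statistics** are min/mean/max of edge weight, great-circle
  distance and chronological distance over the *retained* edges only,
  with the occupation pairs attaining each extreme (first pair under
  ties).
* **Per-unit statistics** use the induced subgraph of a cultural unit's
  occupations (edges to outside nodes do not count). Units of fewer than
  two nodes are undefined and error; units of two nodes have a density
  but no cluster coefficient. Occupations coded `NONE` (outside the named
  cultures) stay in the network but join no unit.
* **Similarity radius**: per within-unit pair, geographic distance ÷
  similarity, aggregated as min/mean/max over full-matrix or
  network-connected pairs. The formula is inferred from the infinity
  pattern of published tables: zero-similarity pairs at positive distance
  give `Inf`, co-located pairs give 0 regardless of similarity, and an
  empty pair set yields the empty-range convention (`min = Inf`,
  `max = −Inf`, `mean = NaN`) — these infinities are in-band values, not
  errors. The formula sits behind one function so an alternative (e.g.
  distance × dissimilarity) can be swapped without touching callers.

### Space, time, sequences

Geographic distance is the haversine great circle on a 6371 km sphere; at
the scale of the Western Mediterranean it stays within 0.3% of an
ellipsoidal geodesic (the test suite verifies 0.5% against Vincenty).
Chronological distance between two calibrated ranges defaults to
`euclidean2d`: the Euclidean distance between (early, late) range vectors
divided by √2, so two ranges offset by d years are d years apart. The raw
Euclidean, overlap-gap and midpoint definitions are available
(`chrono_distance(method=)`); the one-line descriptions in publications
rarely pin the rescaling down, so the method is a recorded configuration
choice rather than a constant.

The three sequence windows (8000–7600, 7650–6800, 7000–6500 cal BP)
deliberately overlap; membership is by closed-interval overlap of the
occupation's date range with each window, and a curated label from the
source dataset always overrides the date-derived assignment, since
overlap-only assignment is not unique for ranges spanning window
boundaries. Consecutive-pair subsets (1–2, 2–3) keep every occupation
whose membership intersects the pair; an occupation in sequence 2 appears
in both.

### Mantel tests

`mantel_test()` correlates the strictly-lower-triangle vectors of two
distance matrices (Pearson) and permutes node labels of one matrix,
recomputing r each draw; `p = (#{r_perm ≥ r_obs} + 1)/(B + 1)`,
one-tailed against positive association — the isolation-by-distance
alternative. The default B = 1000 matches the p-value quanta seen in
published tables (floor 1/1001). The partial test correlates residuals of
X and Y on Z and permutes raw X labels with re-residualization each draw
(one of several published partial-Mantel schemes; it is the documented
method-of-record here). Conditioning on a matrix collinear with Y leaves
a numerically empty residual and raises an error instead of reporting a
noise correlation. The "threshold matrices" variant fixes the mask of
network-connected pairs and re-reads permuted values at those positions.
No multiple-testing correction is applied across the eight-test battery
of `mantel_table()`, by design.

## The synthetic generator

`simulate_assemblage()` emulates the schema and statistical structure of
the real datasets: K cultural units draw trait-frequency profiles from a
symmetric Dirichlet (concentration controls divergence), occupations
scatter around culture-specific spatial centers (default dispersion 120
km), date ranges fall inside per-culture-weighted sequence windows, and
trait values are multinomial counts (default 200 per occupation, 11
traits) or Bernoulli presences (default 88 types, each belonging to one
culture's pool: own-pool probability `base + effect`, defaults
0.05 + 0.35). Setting `distance_decay_strength > 0` blends each
occupation's profile toward a distance-weighted mixture of all culture
profiles (e-folding 300 km), planting an isolation-by-distance signal.
Defaults (3 cultures × 12 occupations) keep thresholds, densities and
edge weights in the same regime as published Early Neolithic networks
while staying fast enough for simulation batteries.

What the generator does *not* emulate: trait evolution through time
(profiles are static within a run), sampling-effort differences between
occupations, spatially correlated dating error, or coastline/route
geometry. Tests passing on synthetic data therefore validate the
*computational* pipeline and its statistical calibration, not the
archaeological interpretation of any particular dataset.

`recovery_experiment()` closes the loop: simulate, run the pipeline, and
measure culture-label assortativity of the threshold network, the Mantel
correlation against the planted decay, and per-culture vs global density.
Note that with few traits, independently drawn Dirichlet profiles can
share a dominant trait by chance, so "well-separated cultures" is
realised explicitly (near-disjoint presence pools, e.g. base rate 0.02
and effect 0.5) rather than assumed of the defaults.

## Numerical choices and degenerate inputs

* Similarity matrices are symmetrized as `(S + Sᵀ)/2` after computation
  and the diagonal set to exactly 1, eliminating 1-ulp asymmetries from
  floating-point distance kernels.
* Threshold selection scans the sorted unique observed weights from the
  top; feasibility is monotone in the threshold, so the first feasible
  candidate is the answer.
* Eigenvector scores use LAPACK's symmetric eigendecomposition; the
  Perron vector's sign is fixed and negligible negative entries clamped
  to 0. Reruns are bit-identical, which the pipeline's byte-identical
  output test relies on.
* Empty edge sets: interval statistics error (there is nothing to
  summarize); edge-list CSV output writes a header-only file; eigenvector
  centrality on an edgeless graph errors.
* Validation never silently drops rows: occupations with missing
  coordinates or dates load flagged, and error messages name the
  offending occupation and trait.

## Validation problem sizes

The test suite checks the threshold rule against a maximum-spanning-tree
bottleneck oracle on 200 random matrices (n ≤ 12); density, betweenness
and transitivity against brute-force enumeration on random graphs
(n ≤ 10); index properties on 1000 random assemblage pairs; Mantel
type-I error on 500 null replicates (n = 30, 199 permutations) with an
acceptance band of [0.03, 0.07] at α = 0.05; and power ≥ 0.8 over 100
seeds against the planted distance-decay alternative. These sizes give
tight Monte-Carlo error while keeping the full suite around a minute.

## Known limitations

* The cluster-coefficient variant and chronological-distance rescaling
  used by any given publication may differ from the defaults here; both
  are configurable precisely because the names alone do not pin them
  down.
* Betweenness centralization follows the documented Freeman formula; see
  the caveat above about reported values that no documented normalization
  reproduces.
* Great-circle distance ignores coastlines: two occupations across a gulf
  are "closer" than any boat journey between them.
* The edge-list CSV format cannot represent isolated nodes; GraphML is
  the lossless format.
* Mantel tests have known sensitivity to spatial autocorrelation within
  matrices; the package implements the standard test, not spatially
  corrected variants.
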