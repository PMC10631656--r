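# asnet — Archaeological Similarity Networks from Trait Assemblages

`asnet` is an R package for archaeologists and cultural-evolution
researchers who want to quantify how material culture was shared between
dated archaeological occupations, and what the structure of that sharing
implies about past interaction networks. It was built around the standard
workflow for Early Neolithic Western Mediterranean pottery decorations and
personal ornaments, but works for any occupation-by-trait table.

## The method

**Similarity.** Two occupations' assemblages are compared with an index on
[0, 1]:

- counts (e.g. decorative-technique tallies): the Brainerd-Robinson index
  on the unit scale,
  `BR(a, b) = 1 − ½ Σ_k |p_ak − p_bk|`,
  where `p_a` are within-assemblage proportions (the classical 0–200
  statistic divided by 200);
- presence/absence (e.g. mutually exclusive bead types): the Jaccard index
  `J(A, B) = |A ∩ B| / |A ∪ B|`.

**Network.** Occupations are nodes; every pair with similarity ≥ a
threshold *t* is joined by an edge weighted by the similarity itself. The
threshold is chosen as the minimum value that keeps the network a single
connected component (optionally tolerating a few extreme outliers) —
equivalently, the bottleneck edge weight of a maximum spanning tree. A
published threshold can also be imposed verbatim.

**Description.** The thresholded network is summarized by density
`2E/(n(n−1))`, cluster coefficient (global transitivity by default,
average-local available), weighted centralities (strength, eigenvector
scaled to mean 1, binarized betweenness), Freeman centralization
normalized by the star-graph maximum, interval statistics (min/mean/max of
edge weight, great-circle km and chronological years over plotted edges),
per-cultural-unit density/clustering, and the intra-cultural *similarity
radius* (geographic distance ÷ similarity per within-unit pair).

**Isolation by distance.** Mantel and partial Mantel permutation tests
correlate cultural distance (1 − similarity) with great-circle and
chronological distances, one-tailed with
`p = (#{r_perm ≥ r_obs} + 1)/(B + 1)`, on full matrices or restricted to
network-connected pairs ("threshold matrices").

**Time sequences.** Occupations carry membership in three time-sequence
windows (8000–7600, 7650–6800, 7000–6500 cal BP); networks for consecutive
pairs (1–2, 2–3) rerun the whole pipeline on the subset.

A synthetic-assemblage generator (`simulate_assemblage()`) plants known
cultural structure — culture-specific trait profiles, spatial centers,
period preferences and an optional distance-decay signal — so every stage
is testable without restricted data, and `recovery_experiment()` measures
how well the planted structure is recovered.

## Worked example

The package ships a small synthetic count dataset
(`inst/extdata/synthetic_counts.csv`: 36 occupations from 3 cultural
units, 11 decorative traits; the filename says synthetic because it is).

```r
library(asnet)

a <- read_assemblage(system.file("extdata", "synthetic_counts.csv",
                                 package = "asnet"), mode = "counts")
a
#> Archaeological assemblage (counts mode)
#>   36 occupations x 11 traits
#>   cultures: CU1, CU2, CU3

S <- similarity_matrix(a)
S
#> BR similarity matrix, 36 occupations
#>   off-diagonal range: 0.2050 - 0.9700 (mean 0.5349)

thr <- connectivity_threshold(S)   # minimum cut keeping one component
as.numeric(thr)
#> [1] 0.445

g  <- build_asn(S, as.numeric(thr), meta = a)
st <- network_stats(g, S = S, distances = distance_matrices(a))
st
#> ASN descriptive statistics
#>   36 nodes, 257 edges (threshold 0.4450)
#>   density 0.4079, cluster coefficient 0.8442
#>   centralization: degree 0.12731, eigen 0.47327, betweenness 0.441
#>   top strength: SYC16:15.7500, SYC17:15.6850, SYC06:15.3250

D <- distance_matrices(a)
mantel_test(cultural_distance(S), D$geo_km, permutations = 999, seed = 1)
#> Mantel test (full matrix)
#>   r = 0.712643, p = 0.001000 (999 permutations, one-tailed, 630 pairs)
```

Reading the output: the auto-selected threshold 0.445 is the weakest
similarity needed to hold all 36 occupations in one component; the 257
retained edges give a moderately dense (0.41), highly clustered (0.84)
network, and the Mantel r of 0.71 (p = 0.001, the floor at 999
permutations) says occupations further apart in space are markedly less
similar — the planted isolation-by-distance structure of this synthetic
dataset.

`run_asn_pipeline()` wraps all of the above plus the time-sequential
subsets and writes a complete output bundle (GraphML, edge lists, CSV
statistic tables, layouts, Mantel tables, provenance YAML);
`inst/scripts/asn_run.R` is a thin command-line wrapper around it.

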