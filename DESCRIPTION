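Package: asnet
Title: Archaeological Similarity Networks from Trait Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses archaeological similarity networks (ASN)
    from occupation-by-trait tables. Computes Brainerd-Robinson (count data)
    and Jaccard (presence/absence) similarities on the [0, 1] scale, selects
    connectivity-preserving edge-weight thresholds, derives descriptive
    network statistics (density, cluster coefficient, weighted centralities
    and Freeman centralization, interval statistics, per-cultural-unit
    statistics and similarity radii), supports time-sequential network
    construction, and tests isolation by distance with Mantel and partial
    Mantel permutation tests on full and threshold-masked distance matrices.
    Includes a synthetic assemblage generator with planted cultural structure
    for validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    geosphere,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    readxl,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
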