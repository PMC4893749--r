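Package: otudyn
Title: Longitudinal 16S Community Dynamics, SparCC Networks and Co-Abundance Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for longitudinal 16S rRNA amplicon studies of
    gut-microbiota dysbiosis: paired-read quality control (quality truncation,
    overlap merging, expected-error filtering), dereplication and greedy 97%
    OTU clustering, rarefaction, alpha diversity and Bray-Curtis principal
    coordinates, one-way PERMANOVA with exact or Monte-Carlo permutations,
    random-forest key-OTU selection by mean decrease in accuracy, SparCC
    compositional basis-correlation estimation with a permutation null,
    correlation-network export, Ward/PERMANOVA co-abundance-group (CAG)
    clustering, CAG trajectory statistics, and nonparametric differential
    abundance testing with Benjamini-Hochberg control. Includes a synthetic
    longitudinal study generator with planted block correlation, treatment
    effects and an invading taxon, used as the recovery oracle throughout.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    randomForest,
    Biostrings,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    biomformat
Config/testthat/edition: 3
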