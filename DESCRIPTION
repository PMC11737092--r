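Package: reefmarkers
Title: Stable Seawater Microbial Indicators of Reef Water Chemistry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines seawater metagenomic count tables (taxa and Gene Ontology
    terms) for microbial indicators of continuous reef physico-chemical
    variables, and quantifies how stable those indicators are. Implements
    compositional preprocessing (rare-feature filtering, centered log-ratio
    transform, hierarchical collapsing), community summaries (Shannon
    diversity, Bray-Curtis within-site similarity, PCA, pairwise PERMANOVA),
    geography-corrected partial Mantel screening of community distances
    against environmental variables, sparse partial least squares (sPLS)
    regression with per-component feature selection, multi-study (MINT)
    integration with leave-one-group-out stability scoring, and repeated
    k-fold cross-validation reselection stability. A synthetic-data
    generator with planted indicator features, functional-redundancy
    structure and trip-level batch effects makes the whole pipeline testable
    without any sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere
Config/testthat/edition: 3
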