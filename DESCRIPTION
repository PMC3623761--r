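Package: epitraject
Title: Developmental Trajectories of Histone Methylation Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies H3K4me3 ChIP-seq signal over promoter-anchored
    genomic regions across an age-structured cohort, detects enriched peaks
    with a local-Poisson sliding-window caller, classifies per-region
    developmental trajectories (up/down between prenatal and older-than-one-
    year samples), resolves cohort structure by PCA on pairwise
    differential-peak counts, clusters max-normalized age profiles with
    k-means, and integrates histone trajectories with CpG methylation
    (hypergeometric anti-correlation contingency) and gene expression.
    Includes a seeded synthetic-cohort generator with planted monotone-
    saturating age kinetics so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
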