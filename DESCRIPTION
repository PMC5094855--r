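Package: guidescreen
Title: Design and Scoring of CRISPRi/CRISPRa sgRNA Libraries and Pooled Screens
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing next-generation CRISPR interference (CRISPRi)
    and activation (CRISPRa) single-guide RNA (sgRNA) libraries and for scoring
    pooled growth screens. Builds hybrid transcription start site (TSS)
    annotations from CAGE peaks and transcript models, enumerates candidate
    protospacers around TSSs, computes position, sequence, RNA-structure and
    chromatin features, linearizes them (binning and kernel position curves)
    and fits an elastic-net activity model, scores genome-wide off-target
    sites with a position-weighted mismatch score and tiered stringency,
    selects sgRNAs per TSS with empirical-evidence priority and generates
    matched negative controls and cloning-ready oligos, and quantifies pooled
    screens (growth phenotypes, Mann-Whitney gene calls, ROC and
    precision-recall evaluation). Seeded synthetic-fixture generators provide
    toy genomes, annotations, chromatin tracks and screens with planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    glmnet,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
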