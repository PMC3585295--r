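Package: CADregulome
Title: Promoter Regulome Analysis of Coronary Artery Disease Biomarker Pathways
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative transcriptional-regulome analysis for coronary artery
    disease (CAD) biomarker pathways. Implements conservation-weighted position
    weight matrix scoring (matrix and core similarity), both-strand promoter
    scanning, TF-by-gene binding-site count matrices, pathway-level set algebra
    identifying core, pathway-specific and combinatorial transcription factors,
    quantile normalization with Welch two-group differential expression, serum
    biomarker fold changes, and a TF-biomarker network with multi-pathway
    modules. Ships a curated binding-count matrix for the five CAD core
    regulators (PPARG, EGR1, ETV1, KLF7, ESRRA) across 31 biomarkers grouped
    into seven pathways, and a fully seeded synthetic-data generator with
    planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcription, GeneRegulation, MotifDiscovery, NetworkInference,
    DifferentialExpression
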