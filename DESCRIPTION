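Package: DevoProteomics
Title: Comparative Developmental Proteome and Transcriptome Analytics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative developmental multi-omics: absolute
    protein concentration estimation from spike-in standards via robust
    Theil-Sen standard curves, protein-complex stoichiometry testing,
    temporal expression-profile analytics (normalization, k-means
    clustering with multiple restarts, RNA-protein correlation,
    stage-transition ranking), reciprocal best-hit orthology,
    cross-species developmental stage-correspondence analysis (stage
    similarity matrices, best-match traces, divergence curves and a
    permutation test for hourglass-shaped divergence), rule-based
    in-silico proteolysis for SNP-robustness assessment, and a
    synthetic-data generator that emulates the statistical structure of
    embryonic time-course proteomes and transcriptomes so every stage
    of the pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, Transcriptomics, TimeCourse, Clustering, Normalization
RoxygenNote: 7.3.3
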