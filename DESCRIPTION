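Package: mesea
Title: Maximum Estimate Score Enrichment and Sex-by-Maternal-Diet Metabolic Profiling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects sex- and maternal-diet-dependent regulation of hepatic
    metabolism from bulk RNA-seq counts, lipidomics intensity tables and
    metabolic phenotyping measurements. Implements the Maximum Estimate Score
    (MES), a running-sum gene-set enrichment statistic over a log2-fold-change
    ranked gene list, with a label-permutation null and Benjamini-Hochberg FDR
    control across pathways; RPKM/CPM/TMM count normalization; lipid species
    grammar parsing with class, carbon-number and double-bond saturation
    profiling and desaturase indices; insulin-sensitivity indices (QUICKI,
    tolerance-test AUC) and MRI/MRS body-composition summaries; and a seeded
    synthetic-data generator emulating the 2x2 sex-by-maternal-diet design so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    car,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneSetEnrichment, RNASeq, Lipidomics, Normalization, Software
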