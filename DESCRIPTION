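Package: transplantScan
Title: Reciprocal-Transplant Expression Scans and Pool-Seq Allele-Frequency
    Tests for Multigenerational Acclimation Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis for reciprocal-transplant RNA-seq studies of
    multigenerational environmental acclimation, as used in copepod ocean
    acidification experiments. Provides isoform-to-unigene collapsing,
    median-of-ratios scale normalization and dispersion/zero gene filters; a
    per-gene ANCOVA scan classifying reaction-norm changes into
    different-slope, different-elevation or both (transgenerational
    plasticity vs. phenotype hypotheses); a logical co-expression pattern
    filter over treatment means; a replicate-stratified
    Cochran-Mantel-Haenszel screen for consistent allele-frequency changes in
    pooled sequencing data (PoPoolation2 sync format) with Bonferroni
    control; hypergeometric GO-term enrichment with
    Benjamini-Yekutieli/Benjamini-Hochberg adjustment; and a seeded
    synthetic-data generator emulating the 14-pool reciprocal-transplant
    design so the whole pipeline can be exercised and validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    jsonlite
biocViews: GeneExpression, Transcriptomics, SNP, Regression, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
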