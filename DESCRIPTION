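Package: evorisk
Title: Attributing Cancer Progression Risk to Tumor Mutational Phenotypes
Version: 0.1.0
Authors@R:
    person("evorisk", "maintainers", email = "maintainers@evorisk.org",
           role = c("aut", "cre"))
Description: A censored-survival analysis pipeline that quantifies how much of
    a tumor cohort's progression risk (overall and disease-free survival) is
    carried by evolutionary features of the mutational phenotype -- cumulative
    mutation-rate features including the 96 trinucleotide substitution
    classes, copy-number and structural-variant rate classes, and clonal
    phylogeny summary statistics -- relative to driver-gene and clinical
    covariates. Provides readers and writers for the on-disk formats involved
    (VCF 4.2 somatic calls, FASTA reference, structured clone-tree files,
    clinical and outcome tables), a Cox proportional-hazards kernel with
    lasso and l0 step-wise forward selection tuned by nested two-loop
    cross-validation, bootstrap feature-importance, permutation controls,
    median-split hazard ratios with log-hazard-ratio fraction attribution,
    and a synthetic-cohort generator with known ground truth so the entire
    pipeline is testable without access to protected tumor sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
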