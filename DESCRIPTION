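Package: renalpgs
Title: Validation of eGFR-Trained Polygenic Scores Against Measured GFR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating polygenic scores developed on estimated
    glomerular filtration rate (eGFR) against directly measured GFR in
    longitudinal population cohorts. Provides a synthetic-cohort generator
    encoding GFR-pathway versus marker-specific (non-GFR) genetic effects on
    serum creatinine and cystatin C, genotype quality control with an exact
    Hardy-Weinberg test and a genomic relationship matrix, the 2009/2012
    CKD-EPI estimating equations, longitudinal BLUP phenotype extraction from
    random-intercept mixed models, PGS Catalog scoring-file parsing and
    allele-harmonized score computation, regression comparisons of PGS effects
    across GFR phenotypes with BCa bootstrap contrasts, per-variant effect
    comparison by Deming (orthogonal) regression, and SNP heritability by
    average-information REML on the genomic relationship matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    splines
Suggests:
    testthat (>= 3.0.0),
    withr,
    boot,
    VariantAnnotation,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
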