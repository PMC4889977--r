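Package: sexqtl
Title: Sex-Specific and X-Linked Regulatory Variation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how sex and the X chromosome shape regulatory
    variation in expression cohorts. Implements sex-specific differential
    expression mean and variance testing (F, Brown-Forsythe and
    residual-based strategies), cis-eQTL and genotype-by-sex interaction
    mapping with hierarchical gene-level false discovery control,
    per-sex cis heritability (proportion of variance explained) by REML
    and Haseman-Elston regression, sex-interacting allele-specific
    expression QTL testing with a binomial generalized linear mixed
    model, negative-binomial differential chromatin accessibility with
    directional integration against expression, and a test for
    cumulatively sex-biased eQTL effect sizes at trait-associated
    variants. X-chromosome genotypes are handled explicitly (male
    hemizygosity, sex-aware allele frequencies). A synthetic-cohort
    generator with known ground truth makes every stage testable without
    access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    vcfR,
    S4Vectors,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    car,
    DESeq2,
    sandwich,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
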