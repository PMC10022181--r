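Package: crossblup
Title: Single-Step Genomic Evaluation for Two-Way Crossbred Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic evaluation of two-way crossbred livestock with three
    single-step GBLUP relationship models: standard ssGBLUP, metafounder
    ssGBLUP (gamma-parameterised ancestral relationships estimated by
    generalised least squares), and breed-specific ssGBLUP built on partial
    pedigree and genomic relationship matrices with breed-of-origin tracing
    of crossbred haplotypes. Includes pedigree and genotype ingestion with
    quality control, bivariate REML variance-component estimation via
    Henderson's mixed model equations, model-based reliabilities (including
    metafounder contrasts), linear-regression (LR) cross-validation
    estimators of bias, dispersion and population accuracy, and a phased
    two-way crossbred simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
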