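Package: hiexpr
Title: Case-Control qRT-PCR Analysis with High-Expressor Subgroup Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Relative quantification of case-control qRT-PCR studies by the
    delta-delta Ct method with geometric-mean housekeeper normalization,
    technical-replicate cleaning and iterative Grubbs population screening;
    a control-anchored high-expressor subgroup estimator whose normal core
    is found by reiterative maximum-removal under a Lilliefors-corrected
    Kolmogorov-Smirnov normality rule; a group-comparison battery (pooled t,
    SPSS-convention Mann-Whitney U, uncorrected 2x2 chi-square, two-way
    ANOVA, one-sample t) with correlation-scale effect sizes; a Spearman
    covariate screen; hierarchical regression decomposition of variance
    into tissue-pH and ligand components; and a seeded synthetic-cohort
    generator so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    car,
    nortest,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
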