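Package: twinkit
Title: Biometric Variance-Component Models for Five-Group Twin Data
Version: 1.0.0
Authors@R: person("Hana", "Yun", email = "hana.yun@example.org",
    role = c("aut", "cre"))
Description: Tools for classical twin analyses of continuous traits measured
    on monozygotic and dizygotic twin pairs in the five-group design (MZ male,
    DZ male, MZ female, DZ female, opposite-sex DZ). Implements skewness-based
    square-root transformation and regression adjustment for sex and age,
    maximum-likelihood twin correlations with profile-likelihood confidence
    intervals, univariate sex-limitation and multivariate Cholesky ACE/ADE
    models estimated by full-information maximum likelihood on raw pair data,
    likelihood-ratio and AIC model comparison, standardized variance
    components and additive/non-additive genetic and environmental
    correlations, and a seeded simulator of five-group twin datasets for
    validation by parameter recovery. Developed around the heritability and
    pleiotropy analysis of Sasang constitution type scores (Tae-Eum, So-Eum,
    So-Yang liabilities on [0,1]).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
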