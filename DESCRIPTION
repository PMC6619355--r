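Package: twinstab
Title: Genetic and Environmental Stability Analysis for Longitudinal Twin Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the classical twin design applied to quantitative
    phenotypes measured at two occasions. Fits bivariate Cholesky ACE/ADE
    decompositions by full-information maximum likelihood over five zygosity
    groups (including opposite-sex pairs and sex-limitation variants),
    constrained saturated models for phenotypic and twin intraclass
    correlations, and model comparison by likelihood-ratio tests and BIC.
    Derives standardized variance components, bivariate covariance
    components, proportions of the phenotypic correlation explained by
    additive genetic, shared and nonshared environmental factors, and
    aetiological correlations from the equivalent correlated-factors
    solution, with profile-likelihood confidence intervals. Also provides
    persistence-subgroup classification by top-decile membership at each
    wave, with Cramer's V, Monte-Carlo Fisher exact tests on fixed-margin
    contingency tables and Cohen's d group contrasts, plus a seeded
    synthetic twin-cohort generator with known ground truth and an
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
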