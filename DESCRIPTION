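Package: spmaging
Title: Stochastic Process Models of Aging Physiology and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint modelling of longitudinal physiological indices and
    mortality with a quadratic-hazard stochastic process model: the
    conditional-Gaussian filtering likelihood for one-dimensional
    mean-reverting dynamics with informative mortality, constrained
    maximum-likelihood estimation with likelihood-ratio comparison of
    genotype groups, age-binned empirical trajectory summaries with
    significance bands, polygenic carrier-count scores analysed by
    left-truncated Cox regression, and a seeded synthetic-cohort
    generator emulating biennial-exam longitudinal studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    survival,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
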