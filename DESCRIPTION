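Package: adheretraj
Title: Dosing-Schedule-Aware Biologic Adherence, Trajectory Clustering, and
    Outcomes for Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring 12-month adherence to injectable biologics in
    longitudinal pharmacy and medical claims, built around the approved dosing
    schedules of the five severe-asthma biologics (benralizumab, dupilumab,
    mepolizumab, omalizumab, tezepelumab). Implements a dosing-schedule state
    machine with a dynamic 7-day buffer, the medication possession ratio (MPR),
    a four-category gap-and-dose-count adherence classifier, group-based
    trajectory modeling of binary adherence series (finite mixtures of
    polynomial-logit trajectories fit by EM with BIC selection), claims-based
    exacerbation and healthcare-resource-utilization phenotyping, pharmacy cost
    aggregation with and without biologic costs, corticosteroid exposure in
    prednisone equivalents, and person-period association models (Poisson and
    negative-binomial mixed count models, linear mixed cost models, SMDs). A
    synthetic claims cohort generator with heterogeneous adherence archetypes
    and adherence-dependent event rates makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
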