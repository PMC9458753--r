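Package: resistfam
Title: Model-Family Analysis of Targeted-Therapy Resistance from Tumor
    Volume Time Courses
Version: 0.1.0
Authors@R:
    person("resistfam", "developers", email = "resistfam@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring the timing and mechanism of resistance to
    targeted cancer therapy from longitudinal tumor-volume measurements in
    patient-derived xenografts. Provides a family of ordinary differential
    equation models of sensitive/resistant tumor dynamics under impulsive
    weekly dosing, a two-stage fitter combining a Sobol quasi-Monte Carlo
    global search with stochastic gradient descent refinement, AIC/BIC model
    selection with confidence tiers, profile-likelihood identifiability
    analysis of the initial resistance fraction, simulated dose-escalation
    experiments, and a synthetic-cohort generator with known ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
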