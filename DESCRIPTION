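Package: centerprofile
Title: Bayesian Profiling of Treatment Centers for Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian logistic regression with center-level random
    intercepts for profiling treatment centers on a binary patient outcome, such
    as receipt of a kidney transplant within two years of starting kidney
    replacement therapy. Posterior sampling uses a Metropolis-Hastings-within-Gibbs
    algorithm with random-walk (optionally gradient-informed) proposals for the
    intercept, fixed effects and center effects, and an exact conjugate
    Inverse-Gamma draw for the between-center variance. Downstream tools compute
    model-based standardized incidence ratios (SIR) with credible intervals,
    funnel plots with conventional and false-discovery-rate-adjusted control
    limits, empirical-Bayes shrinkage summaries, Gelman-Rubin and effective sample
    size convergence diagnostics, and posterior predictive ROC/AUC checks. A
    synthetic cohort generator emulating a national dialysis-and-transplant
    registry makes the whole pipeline exercisable without confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
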