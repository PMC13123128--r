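# centerprofile

Bayesian profiling of treatment centers on a binary patient outcome —
built for the registry question "which dialysis/transplant centers
transplant their patients within two years of starting kidney replacement
therapy more or less often than their case-mix predicts?", and usable for
any center-vs-outcome comparison with categorical case-mix covariates.

## The model

For patient *i* at center *j(i)*:

```
logit P(y_i = 1) = α + x_iᵀβ + u_{j(i)},   u_j ~ N(0, σ²_u)
α ~ N(0, σ²_α),  β_k ~ N(0, Σ_β[k]),  σ²_u ~ IG(a₀, b₀)
```

The posterior is sampled by a Metropolis-Hastings-within-Gibbs algorithm:
random-walk (optionally Langevin/MALA) Metropolis updates for α, each β_k
and each u_j against their log full conditionals, and an exact conjugate
draw σ²_u | u ~ IG(a₀ + J/2, b₀ + ½Σu²). Proposal scales adapt during
burn-in only, targeting 20–40% acceptance. The chain loop is compiled
(Rcpp) and verified draw-for-draw against a plain-R reference engine.

Downstream, each center gets a standardized incidence ratio
SIR_j = (O_j + ε)/(E_j + ε) with E_j the posterior-mean model-expected
count and ε = 1e-6 keeping zero-event centers finite; credible intervals
from per-draw ratios; funnel plots of log-SIR against precision 1/√E_j
with conventional (μ ± z·σ_j) and Benjamini-Hochberg FDR-adjusted control
limits; shrinkage summaries (empirical vs model-shrunken logit, percent
moved toward the group mean, by volume tertile); Gelman-Rubin PSRF and
Geyer-truncated effective sample sizes; and posterior predictive ROC/AUC.

Because the motivating registry extract is confidential, the package ships
a synthetic cohort generator (`simulate_cohort()`) reproducing its
published marginal structure — 34 centers split into Indigenous/
non-Indigenous sub-centers, ~17,000 patients, ~12% event prevalence,
sparse covariates, zero-event centers — with known ground truth, so the
whole pipeline is testable end to end.

## Worked example

```r
library(centerprofile)

sim <- simulate_cohort(total_patients = 4000, seed = 42)
fit <- mwg_logit(
  outcome ~ sex + age_group + indigenous + lung_disease + diabetes +
    cvd + late_referral + obesity + mmm + period,
  sim$data, center = "center",
  control = mwg_control(n_iter = 6000, burn_in = 1500, n_chains = 3),
  seed = 42)

summary(fit)$fixed[c("sexMale", "diabetesYes"), ]
#>              mean   sd  q2.5 ...  q97.5   or or_lower or_upper
#> sexMale      0.05 0.10 -0.14 ...   0.24 1.05     0.87     1.27
#> diabetesYes -1.07 0.10 -1.28 ...  -0.87 0.34     0.28     0.42
```

The `or` column is the odds ratio `exp(mean)` with exponentiated credible
bounds: here diabetes cuts the odds of transplant within two years to about
a third (OR 0.34, 95% CrI 0.28–0.42), recovering the generating coefficient
(−1.08 log-odds).

```r
prof <- center_profiles(fit, max_draws = 2000)
prof
#> Center profiles (34 centers; 14 flagged by CrI, 12 by FDR limits)
#>      N   O      E log_sir log_sir_sd cri_2.5 cri_97.5  sir
#> 1   15   0   0.54  -13.20       0.62  -14.09   -11.71 0.00
#> 2   21   1   2.73   -1.00       0.33   -1.49    -0.19 0.37
#> ...
#> 16 787 126 125.15    0.01       0.07   -0.13    0.16 1.01

plot(prof)         # funnel plot with conventional + FDR limits
shrinkage_table(fit)
convergence_table(fit)
posterior_predictive_auc(fit)
```

A log-SIR of 0 means a center's observed count matches its case-mix
expectation; the zero-event centers land near −13 under the ε-rule rather
than −∞ and are classified below expectation. `run_pipeline()` chains
simulate → fit → diagnose → profile → shrinkage → predictive check and
writes every table to an output directory with a reproducibility manifest;
`inst/cli/centerprofile.R` exposes the same steps as shell subcommands.

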