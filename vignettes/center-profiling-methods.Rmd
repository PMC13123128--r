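---
title: "Bayesian center profiling: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian center profiling: model, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Registries that follow patients with end-stage kidney disease want to know
whether some treatment centers transplant their patients within two years of
starting kidney replacement therapy substantially more or less often than
their case-mix predicts. Raw event rates are misleading: centers differ in
patient age, comorbidity, remoteness and era, and small centers produce
noisy rates. `centerprofile` implements the standard answer from the
provider-profiling literature — a hierarchical ("random intercept") logistic
regression fitted by MCMC, followed by model-based standardized incidence
ratios (SIR), funnel plots and shrinkage summaries — with the posterior
obtained from a purpose-built Metropolis-Hastings-within-Gibbs sampler.

## The model

For patient $i$ treated at center $j[i]$,

$$\mathrm{logit}\,P(y_i = 1) \;=\; \eta_i \;=\; \alpha + x_i^\top \beta + u_{j[i]},
\qquad u_j \sim N(0, \sigma^2_u),$$

with priors $\alpha \sim N(0, \sigma^2_\alpha)$, $\beta_k \sim N(0,
\Sigma_{\beta,kk})$ (independent components) and $\sigma^2_u \sim
\mathrm{IG}(a_0, b_0)$ with density $\propto x^{-(a_0+1)} e^{-b_0/x}$
(so $b_0$ is a rate: the precision $1/\sigma^2_u$ is Gamma$(a_0, b_0)$).
Defaults are $a_0 = b_0 = 1$, the traditional variance-component choice that
keeps the Gibbs update for $\sigma^2_u$ exact, and $\sigma^2_\alpha =
\Sigma_{\beta,kk} = 100$ — weakly informative on the log-odds scale, where
effects beyond $\pm 10$ are not meaningful. All are user-overridable through
`mwg_prior()`.

The logistic likelihood is not conjugate with Gaussian priors, so the
sampler cycles Metropolis steps through the log full conditionals

$$\log P(\alpha \mid \cdot) = \sum_i \big[y_i\eta_i - \log(1+e^{\eta_i})\big]
  - \frac{\alpha^2}{2\sigma^2_\alpha},$$

and their analogues for each $\beta_k$ and each $u_j$ (the $u_j$ conditional
sums only over center $j$'s patients), while $\sigma^2_u$ is drawn exactly
from its conjugate full conditional
$\mathrm{IG}\!\big(a_0 + J/2,\; b_0 + \tfrac12\sum_j u_j^2\big)$.
The package exposes every conditional and its gradient
(`log_conditional_alpha()`, `grad_beta()`, ...) so each can be verified
against the joint posterior and against finite differences — the test suite
does both.

## The sampler

One iteration updates, in order: $\alpha$; each $\beta_k$ in ascending
index order; each $u_j$; then the exact $\sigma^2_u$ draw. The default
proposal is a symmetric random walk $\theta^* \sim N(\theta, \tau^2)$
accepted with probability $\min(1, e^{\Delta})$; a gradient-informed
Langevin-style kernel (proposal mean offset by $\tfrac{\tau^2}{2}\nabla$,
with the corresponding asymmetric-proposal correction) is available via
`mwg_control(kernel = "mala")`. The production loop is compiled (Rcpp), and
a plain-R reference loop consumes the random-number stream identically —
the two are tested to be draw-for-draw identical, which pins the compiled
code to the readable reference semantics.

Choices the protocol leaves open, and what this package does:

* **Run length.** Defaults are 3 chains of 20,000 iterations, 2,000
  burn-in, thinning 1 — 18,000 retained per chain, 54,000 pooled.
* **Initial values** (not dictated by the protocol): chain 1 starts at the
  pooled empirical log-odds with zero effects and $\sigma^2_u = 1$; later
  chains jitter $\alpha$ and $\beta$ by $N(0, 0.5^2)$ so the Gelman-Rubin
  diagnostic sees genuinely overdispersed starts.
* **Proposal scales.** Initial scales default to each block's
  inverse-square-root Bernoulli information at the pooled event rate
  ($\tau \approx 2.4/\sqrt{n_{\mathrm{block}}\bar p(1-\bar p)}$, clamped to
  $[0.02, 2.5]$) — the scale a short pilot run would land on. During
  burn-in only, every 100 iterations each block's $\tau$ is multiplied by
  1.1 if its window acceptance exceeded 40% and divided by 1.1 below 20%,
  targeting the 20-40% band; adaptation freezes at the end of burn-in so
  the retained draws come from a fixed-kernel chain with the correct
  invariant distribution. A flat initial scale (for example 0.1 everywhere)
  is available through `proposal_sd`, but with the gentle 1.1-per-window
  factor it cannot reach the scales weakly-informed blocks need within a
  2,000-iteration burn-in, which is why the information-based start is the
  default.
* **RNG.** One master seed; chains get disjoint L'Ecuyer-CMRG substreams,
  so runs are reproducible and chains independent.

## Diagnostics

`convergence_table()` reports the classic (unsplit) Gelman-Rubin PSRF
($\hat V/W$ form; a split-chain variant is available) and an effective
sample size using Geyer's initial-positive-sequence truncation of the
autocorrelation sum, computed by FFT. Note the unsplit PSRF estimator is
bounded below by $\sqrt{(n-1)/n}$, not by 1, and values a hair under 1 are
normal for well-mixed chains. The working stability rule for this model
family is PSRF $\approx$ 1.0 and ESS $> 200$; `run_pipeline()` warns when a
parameter misses it. Intercept/random-effect correlation makes $\alpha$ the
slowest-mixing parameter in this model (no centering reparameterization is
applied), and covariates whose minority level is rare or nearly event-free
(cardiovascular disease, Indigenous status in cohorts of this shape) mix
slowest among the $\beta$'s — expect modest ESS for those.

`posterior_predictive_auc()` scores, per retained draw, the ROC AUC
(Mann-Whitney with midrank ties) of predicted probabilities against the
observed outcomes, reporting quantiles over draws plus the AUC of the
draw-averaged probabilities.

## Center profiling

With retained draws $s = 1,\dots,S$: per-patient probabilities
$p_i^{(s)} = \sigma(\alpha^{(s)} + x_i^\top\beta^{(s)} + u_{j[i]}^{(s)})$,
per-center expected counts $E_j^{(s)} = \sum_{i: j[i]=j} p_i^{(s)}$ averaged
to $E_j$ (the per-draw sums are averaged, not summed — the only definition
on the count scale), and

$$\mathrm{SIR}_j = \frac{O_j + \epsilon}{E_j + \epsilon}, \qquad
\epsilon = 10^{-6},$$

with $\epsilon$ in numerator and denominator so zero-event centers get a
finite, extremely negative log-SIR (about $-13$ to $-14$ at realistic
$E_j$) instead of $-\infty$, while non-zero centers move only at order
$\epsilon$. Credible intervals are quantiles of the per-draw ratios
$(O_j+\epsilon)/(E_j^{(s)}+\epsilon)$; log-scale bounds are logs of the same
quantiles (quantiles commute with monotone maps, so the two readings of the
interval coincide). The variance of $\log \mathrm{SIR}_j$ is the posterior
sample variance of the per-draw log ratios: $O_j$ is a fixed observed
constant, so its nominal variance and covariance contributions are exactly
zero under this estimator; a Poisson/delta-method approximation is exposed
via `var_log_sir(method = "delta")` for comparison.

Funnel limits at level $\alpha$ are $\mu \pm z_{1-\alpha/2}\sigma_j$ with
$\mu = 0$ on the log-SIR scale (overridable). FDR-adjusted limits apply the
Benjamini-Hochberg step-up to $p_j = 2\Phi(-|\log\mathrm{SIR}_j|/\sigma_j)$:
the largest $k$ with $p_{(k)} \le (k/m)q$ sets
$z_{\mathrm{FDR}} = \Phi^{-1}(1 - p_{(k)}/2)$ and limits
$\pm z_{\mathrm{FDR}}\sigma_j$. Two branches the recipe leaves open: when
no center passes the step-up, the package flags nothing, reports the
conventional $z_{1-\alpha/2}$ and sets a `no_signals` flag; zero-event
centers enter the p-value pool like any other (their enormous
$|\log\mathrm{SIR}|/\sigma$ makes them near-certain signals), which is the
transparent default. A point exactly on a limit is classified "within"
(conservative flagging). On the funnel-curve grid the limit curves use
$\sigma \approx 1/\sqrt{E}$, the usual approximation that makes the funnel
narrow as precision grows; each center's in/out flag uses its own
$\sigma_j$.

## Shrinkage summaries

`shrinkage_table()` quantifies partial pooling per center: the empirical
logit $\log\{(O_j + 0.5)/(N_j - O_j + 0.5)\}$ (Haldane-Anscombe correction,
finite at 0 and $N_j$ events), the model-shrunken logit
$\mathrm{logit}(E_j/N_j)$, the distance between them, and the percent of
the center's distance from the group-mean logit removed by shrinkage
(negative when the model pushes a center outward — seen for some large
centers). The group mean is the unweighted mean of empirical logits by
default (a volume-weighted version is available); volume categories are
tertiles of $N_j$ with ties broken by input order. These are this package's
operationalizations of the named metrics — the source protocol names them
without formulas — and they are documented as such.

## The synthetic registry generator

Because the motivating registry extract is confidential, `simulate_cohort()`
generates cohorts with its published marginal structure: 34 centers labelled
alphabetically and split into Indigenous ("I") and non-Indigenous ("N")
sub-centers, log-normally dispersed center sizes (tens to ~2,500 patients,
~17,000 total, the I sub-centers holding ~4%), covariate frequencies
matching the published margins (60% male, age skewed older, 0.4%
cardiovascular disease, 45% diabetes, metropolitan-dominated remoteness),
true coefficients set to the published posterior means
(`registry_effect_sizes()`), $\sigma_u = 0.4$, and two small I centers
forced to $u_j = -6$ so the zero-event edge cases downstream are always
exercised. Forcing $u_j$ rather than post-hoc editing outcomes keeps the
cohort model-coherent; `inject_zero_event_center()` is the blunt
alternative for targeted tests. The `indigenous` covariate follows the
sub-center type (that is what the I/N split means); all other covariates
are drawn independently per patient — a deliberate simplification, so the
generator reproduces the registry's margins but not its joint
covariate structure.

The default intercept is $-1.72$, calibrated once, numerically, so that the
default configuration reproduces the registry's ~12% marginal prevalence
under this covariate mix (the published reference intercept describes a
reference-category patient, not the cohort average; with the covariate
margins above it would imply a ~5-7% cohort prevalence).

What passing tests on these cohorts shows: the sampler recovers parameters
it generated, conservation and coherence identities hold, and the profiling
pipeline behaves at the registry's scale and sparsity. What it cannot show:
robustness to correlated covariates, informative center-size/case-mix
dependence, or any model misspecification present in real registry data.

## Verification strategy and problem sizes

The suite checks every analytic gradient against central finite
differences, every block conditional against the joint posterior, the
conjugate update against a grid normalization, the sampler against
grid-integrable posteriors (Kolmogorov-Smirnov distance on $\ge$ 50,000
pooled draws for a two-parameter model), the FDR step-up against an
exhaustive-$k$ oracle, and the AUC against an all-pairs count. The
simulation studies use 20 replicate cohorts of ~2,000 patients across 34
centers fitted with 3 chains $\times$ 10,000 iterations — sizes chosen so
the whole study runs in minutes on one core while leaving the coverage and
shrinkage comparisons well-powered; the full protocol-scale run
(~17,000 patients, 3 $\times$ 20,000) takes a few minutes more and is what
`run_pipeline()` does by default.

## Known limitations

* Random-walk/MALA updates on the natural parameterization: no centering or
  Polya-Gamma augmentation, so the intercept mixes slowly when $J$ is small
  relative to the center-effect scale. Thin or extend chains if its ESS
  matters for your use.
* Categorical covariates only (dummy coding); continuous covariates would
  pass through the design matrix but the loaders treat everything declared
  as categorical.
* No league-table or rank-based inference, and no indirect standardization
  against an external reference population — expectations are always
  model-based.
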