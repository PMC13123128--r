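# shared fixtures, all generated in code

# small random cohort with known dimensions
tiny_cohort <- function(n = 60, J = 3, p = 2, seed = 1, rate = 0.3) {
  set.seed(seed)
  X <- if (p > 0) matrix(rbinom(n * p, 1, 0.5), n, p,
                         dimnames = list(NULL, paste0("x", seq_len(p))))
       else matrix(numeric(0), n, 0)
  ci <- if (J > 0) sort(rep_len(seq_len(J), n)) else NULL
  y <- rbinom(n, 1, rate)
  cohort_data(y, X, ci)
}

random_state <- function(p, J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  param_state(alpha = rnorm(1), beta = rnorm(p), u = rnorm(J),
              sigma2_u = rexp(1) + 0.1)
}

# the model formula of the synthetic registry generator
registry_formula <- outcome ~ sex + age_group + indigenous + lung_disease +
  diabetes + cvd + late_referral + obesity + mmm + period

# memoised small synthetic fit reused by diagnostics/profiling/shrinkage tests
.fixture_env <- new.env(parent = emptyenv())
cached_small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- simulate_cohort(n_centers = 12, total_patients = 1500, seed = 99)
    .fixture_env$sim <- sim
    .fixture_env$fit <- mwg_logit(
      outcome ~ sex + age_group + diabetes + late_referral, sim$data,
      center = "center",
      control = mwg_control(n_iter = 3000, burn_in = 600, n_chains = 2),
      seed = 7)
  }
  list(fit = .fixture_env$fit, sim = .fixture_env$sim)
}

# deterministic stand-in fit with draws chosen by the test
fake_fit <- function(alpha, beta, u, sigma2_u = NULL, cohort) {
  S <- length(alpha)
  beta <- if (cohort$n_covariates > 0)
    matrix(beta, S, cohort$n_covariates,
           dimnames = list(NULL, colnames(cohort$X)))
  else matrix(numeric(0), S, 0)
  u <- if (cohort$n_centers > 0)
    matrix(u, S, cohort$n_centers,
           dimnames = list(NULL, cohort$center_labels))
  else matrix(numeric(0), S, 0)
  ch <- list(alpha = alpha, beta = beta, u = u,
             sigma2_u = sigma2_u %||% rep(1, S), S = S)
  draws <- structure(list(chains = list(ch), n_chains = 1,
                          coef_names = colnames(cohort$X),
                          center_labels = cohort$center_labels),
                     class = "mwg_draws")
  structure(list(draws = draws, cohort = cohort,
                 control = mwg_control(n_iter = 2 * S, burn_in = S)),
            class = "mwg_logit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
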