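#' Fit a hierarchical logistic regression by Metropolis-within-Gibbs
#'
#' Fits the Bayesian hierarchical logistic model
#' \deqn{\mathrm{logit}\,P(y_{j[i]}=1) = \alpha + x_i^\top\beta + u_{j[i]},
#'   \qquad u_j \sim N(0, \sigma^2_u),}
#' with Gaussian priors on \eqn{\alpha} and \eqn{\beta} and an Inverse-Gamma
#' prior on \eqn{\sigma^2_u}, by a Metropolis-Hastings-within-Gibbs sampler:
#' random-walk (or optionally Langevin-style gradient-informed) Metropolis
#' updates for the intercept, each coefficient and each center effect, and an
#' exact conjugate Inverse-Gamma Gibbs draw for the between-center variance.
#' This is the model behind standardized-incidence-ratio profiling of
#' treatment centers on a binary outcome such as kidney transplant within two
#' years of starting kidney replacement therapy.
#'
#' @param formula model formula `outcome ~ covariates`; the outcome must be
#'   binary (0/1, logical, or a two-level factor) and covariates are
#'   typically factors, dummy-coded against their first (reference) level.
#' @param data a data frame, e.g. the `data` element of [simulate_cohort()]
#'   or a file read via [load_cohort()].
#' @param center name of the center identifier column (string or one-sided
#'   formula), or `NULL` to fit a model without center effects.
#' @param prior an [mwg_prior].
#' @param control an [mwg_control]; the defaults are the full published
#'   protocol (3 chains of 20,000 iterations) — scale down for interactive
#'   use.
#' @param seed master RNG seed; chains receive disjoint substreams.
#' @param engine `"cpp"` (compiled loop, default) or `"r"` (reference loop).
#'
#' @return An object of class `"mwg_logit"` with components `draws` (an
#'   `"mwg_draws"` object), `cohort` (the [cohort_data]), `acceptance`
#'   (per-block post-burn-in acceptance rates per chain), `prior`, `control`,
#'   `seed` and `call`. Methods: `print`, `summary`, `coef`, `fitted`,
#'   `predict`, `residuals`, `simulate`, `plot`.
#' @seealso [center_profiles()], [shrinkage_table()], [convergence_table()],
#'   [posterior_predictive_auc()]
#' @examples
#' sim <- simulate_cohort(n_centers = 6, total_patients = 600, seed = 1)
#' fit <- mwg_logit(outcome ~ sex + diabetes, sim$data, center = "center",
#'                  control = mwg_control(n_iter = 500, burn_in = 100,
#'                                        n_chains = 2), seed = 1)
#' fit
#' @export
mwg_logit <- function(formula, data, center = NULL, prior = mwg_prior(),
                      control = mwg_control(), seed = NULL,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cohort <- if (inherits(data, "cohort_data")) data
            else build_cohort(formula, data, center)
  draws <- run_chains(cohort, prior, control, seed = seed, engine = engine)
  acc <- lapply(draws$chains, function(ch) {
    denom <- ch$n_post %||% (control$n_iter - control$burn_in)
    list(alpha = ch$accept_alpha / denom,
         beta = ch$accept_beta / denom,
         u = ch$accept_u / denom)
  })
  structure(list(draws = draws, cohort = cohort, acceptance = acc,
                 prior = prior, control = control, seed = draws$seed,
                 call = match.call()),
            class = "mwg_logit")
}

#' @export
print.mwg_logit <- function(x, ...) {
  S <- sum(vapply(x$draws$chains, function(ch) ch$S, integer(1)))
  cat("Hierarchical Bayesian logistic regression (Metropolis-within-Gibbs)\n")
  cat(sprintf("  %d patients, %d centers, %d fixed effects\n",
              x$cohort$n_patients, x$cohort$n_centers, x$cohort$n_covariates))
  cat(sprintf("  %d chains x %d iterations (burn-in %d, thin %d): %d retained draws\n",
              x$control$n_chains, x$control$n_iter, x$control$burn_in,
              x$control$thin, S))
  cat("\nPosterior means (log-odds):\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.mwg_logit <- function(object, ...) {
  pooled <- pool_draws(object)
  cols <- c("alpha", grep("^beta\\.", colnames(pooled), value = TRUE))
  cm <- colMeans(pooled[, cols, drop = FALSE])
  names(cm) <- sub("^beta\\.", "", names(cm))
  names(cm)[1] <- "(Intercept)"
  cm
}

#' Posterior summaries in the reporting schema
#'
#' Pools the retained draws across chains and tabulates mean, SD and the
#' 2.5/25/50/75/97.5% quantiles per parameter; for fixed effects an
#' exponentiated (odds-ratio) column with exponentiated 2.5/97.5% bounds is
#' appended, computed from the unrounded draws.
#'
#' @param object a fitted [mwg_logit] model.
#' @param ... unused.
#' @return An object of class `"summary.mwg_logit"` with elements `fixed`,
#'   `random`, `sigma_u` (summary tables), `diagnostics` (PSRF/ESS) and
#'   `acceptance`.
#' @export
summary.mwg_logit <- function(object, ...) {
  pooled <- pool_draws(object)
  fx_cols <- c("alpha", grep("^beta\\.", colnames(pooled), value = TRUE))
  u_cols <- grep("^u\\.", colnames(pooled), value = TRUE)
  fixed <- posterior_summary(pooled[, fx_cols, drop = FALSE], exponentiate = TRUE)
  rownames(fixed) <- c("(Intercept)", sub("^beta\\.", "", fx_cols[-1]))
  random <- if (length(u_cols))
    posterior_summary(pooled[, u_cols, drop = FALSE]) else NULL
  if (!is.null(random)) rownames(random) <- sub("^u\\.", "", u_cols)
  sig <- posterior_summary(pooled[, "sigma2_u", drop = FALSE])
  rownames(sig) <- "sigma2_u"
  diag <- convergence_table(object)
  out <- list(fixed = fixed, random = random, sigma_u = sig,
              diagnostics = diag, acceptance = object$acceptance,
              control = object$control)
  class(out) <- "summary.mwg_logit"
  out
}

#' @export
print.summary.mwg_logit <- function(x, digits = 2, ...) {
  cat("Fixed effects (log-odds and odds-ratio scale):\n")
  print(round(x$fixed, digits))
  cat("\nBetween-center variance:\n")
  print(round(x$sigma_u, digits + 1))
  if (!is.null(x$diagnostics)) {
    worst <- x$diagnostics[which.max(x$diagnostics$psrf), , drop = FALSE]
    cat(sprintf("\nConvergence: max PSRF %.3f (%s), min ESS %.0f (%s)\n",
                max(x$diagnostics$psrf, na.rm = TRUE),
                rownames(worst),
                min(x$diagnostics$ess, na.rm = TRUE),
                rownames(x$diagnostics)[which.min(x$diagnostics$ess)]))
  }
  invisible(x)
}

#' @export
fitted.mwg_logit <- function(object, ...) {
  colMeans(predict_probs(object))
}

#' Posterior predictions from a fitted model
#'
#' @param object a fitted [mwg_logit].
#' @param newdata optional data frame with the same covariate and center
#'   columns as the training data (centers must be known to the fit).
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param draws if `TRUE` return the per-draw matrix (draws x patients);
#'   otherwise the posterior mean per patient.
#' @param ... unused.
#' @export
predict.mwg_logit <- function(object, newdata = NULL,
                              type = c("response", "link"), draws = FALSE, ...) {
  type <- match.arg(type)
  cohort <- if (is.null(newdata)) object$cohort
            else build_cohort_like(object, newdata)
  eta <- predict_eta(object, cohort)
  out <- if (type == "response") stats::plogis(eta) else eta
  if (draws) out else colMeans(out)
}

# rebuild a cohort for newdata using the training encoding/center labels
build_cohort_like <- function(object, newdata) {
  fml <- stats::formula(object$call$formula)
  center_arg <- object$call$center
  center <- if (is.null(center_arg)) NULL else eval(center_arg)
  if (!is.null(center) && is.character(center)) {
    bad <- setdiff(unique(as.character(newdata[[center]])),
                   object$cohort$center_labels)
    if (length(bad))
      stop(sprintf("center(s) not in the fitted model: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    newdata[[center]] <- factor(as.character(newdata[[center]]),
                                levels = object$cohort$center_labels)
  }
  co <- build_cohort(fml, newdata, center)
  if (!identical(colnames(co$X), object$draws$coef_names))
    stop("newdata design columns do not match the fitted model", call. = FALSE)
  co$center_labels <- object$cohort$center_labels
  co$n_centers <- object$cohort$n_centers
  co
}

#' @export
residuals.mwg_logit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  p <- fitted(object)
  r <- object$cohort$y - p
  if (type == "pearson") r / sqrt(p * (1 - p)) else r
}

#' @export
simulate.mwg_logit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    pr <- predict_probs(object)
    S <- nrow(pr)
    idx <- sample.int(S, nsim, replace = nsim > S)
    out <- t(vapply(idx, function(s) stats::rbinom(ncol(pr), 1, pr[s, ]),
                    integer(ncol(pr))))
    as.data.frame(t(out))
  })
}

#' Trace and density plots for a fitted model
#'
#' @param x a fitted [mwg_logit].
#' @param pars parameter names (columns of [pool_draws()]); default the
#'   intercept, the first few coefficients and `sigma2_u`.
#' @param type `"trace"` or `"density"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.mwg_logit <- function(x, pars = NULL, type = c("trace", "density"), ...) {
  type <- match.arg(type)
  pooled <- pool_draws(x)
  if (is.null(pars))
    pars <- utils::head(c("alpha", grep("^beta\\.", colnames(pooled), value = TRUE),
                          "sigma2_u"), 6)
  pars <- intersect(pars, colnames(pooled))
  old <- graphics::par(mfrow = c(ceiling(length(pars) / 2), min(2, length(pars))),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  S <- x$draws$chains[[1]]$S
  for (pn in pars) {
    if (type == "trace") {
      graphics::plot(pooled[seq_len(S), pn], type = "l", col = 1,
                     main = pn, xlab = "", ylab = "", ...)
      for (ch in seq_along(x$draws$chains)[-1])
        graphics::lines(pooled[(ch - 1) * S + seq_len(S), pn], col = ch)
    } else {
      graphics::plot(stats::density(pooled[, pn]), main = pn, xlab = "", ...)
    }
  }
  invisible(x)
}
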