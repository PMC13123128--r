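#' Prior hyperparameters for the hierarchical logistic model
#'
#' The model places independent Gaussian priors on the intercept and each
#' fixed-effect coefficient, Gaussian center effects \eqn{u_j \sim N(0,
#' \sigma^2_u)}, and a conjugate Inverse-Gamma prior on the between-center
#' variance, \eqn{\sigma^2_u \sim IG(a_0, b_0)} with density proportional to
#' \eqn{x^{-(a_0+1)} e^{-b_0/x}} (so `b0` is a rate).
#'
#' @param sigma2_alpha prior variance of the intercept (log-odds scale).
#'   Default 100, weakly informative.
#' @param sigma2_beta prior variance of each fixed effect; scalar (recycled)
#'   or length-p vector — the prior covariance is diagonal.
#' @param a0,b0 Inverse-Gamma shape and rate for \eqn{\sigma^2_u}; default 1
#'   and 1, the traditional variance-component choice that keeps the Gibbs
#'   update exact.
#'
#' @return A list of class `"mwg_prior"`.
#' @export
mwg_prior <- function(sigma2_alpha = 100, sigma2_beta = 100, a0 = 1, b0 = 1) {
  stopifnot(sigma2_alpha > 0, all(sigma2_beta > 0), a0 > 0, b0 > 0)
  structure(list(sigma2_alpha = sigma2_alpha, sigma2_beta = sigma2_beta,
                 a0 = a0, b0 = b0), class = "mwg_prior")
}

# recycle the beta prior variance to length p
beta_prior_var <- function(prior, p) {
  v <- rep_len(prior$sigma2_beta, p)
  if (p > 0 && length(prior$sigma2_beta) != 1 && length(prior$sigma2_beta) != p)
    stop("sigma2_beta must be scalar or length p", call. = FALSE)
  v
}

#' One point in parameter space
#'
#' @param alpha intercept (log-odds).
#' @param beta length-p fixed-effect vector.
#' @param u length-J vector of center random intercepts.
#' @param sigma2_u between-center variance (> 0).
#' @return A list of class `"param_state"`.
#' @export
param_state <- function(alpha = 0, beta = numeric(0), u = numeric(0),
                        sigma2_u = 1) {
  if (sigma2_u <= 0) stop("sigma2_u must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = as.numeric(beta), u = as.numeric(u),
                 sigma2_u = sigma2_u), class = "param_state")
}

#' Numerically stable logistic function
#'
#' \eqn{\sigma(\eta) = 1/(1+e^{-\eta})}, the inverse of the logit link; safe
#' for \eqn{|\eta|} up to several hundred.
#'
#' @param eta numeric vector of linear predictors (finite).
#' @return Probabilities in `[0, 1]`.
#' @export
logistic <- function(eta) {
  stopifnot_finite(eta, "linear predictor")
  stats::plogis(eta)
}

#' Linear predictor of the hierarchical logistic model
#'
#' \eqn{\eta_i = \alpha + x_i^\top \beta + u_{j[i]}} for every patient.
#'
#' @param state a [param_state].
#' @param data a [cohort_data].
#' @return Numeric vector of length `n_patients`.
#' @export
linear_predictor <- function(state, data) {
  if (length(state$beta) != data$n_covariates)
    stop("beta length does not match design matrix", call. = FALSE)
  if (length(state$u) != data$n_centers)
    stop("u length does not match number of centers", call. = FALSE)
  eta <- rep(state$alpha, data$n_patients)
  if (data$n_covariates > 0) eta <- eta + drop(data$X %*% state$beta)
  if (data$n_centers > 0) eta <- eta + state$u[data$center_index]
  eta
}

#' Bernoulli log-likelihood on the logit scale
#'
#' \eqn{\sum_i [y_i \eta_i - \log(1 + e^{\eta_i})]}, computed with
#' `log1p`-style stability so that \eqn{\eta} in \eqn{[-700, 700]} is safe.
#'
#' @param y binary outcome vector.
#' @param eta linear predictor vector of the same length.
#' @return Scalar log-likelihood.
#' @export
bernoulli_loglik <- function(y, eta) {
  if (length(y) != length(eta)) stop("length mismatch", call. = FALSE)
  sum(y * eta - log1pexp(eta))
}

#' Log full conditionals and gradients of the parameter blocks
#'
#' The Metropolis-within-Gibbs sampler targets, in turn, the full conditional
#' density of each block of \eqn{(\alpha, \beta, u, \sigma^2_u)}. These
#' functions evaluate the log full conditionals (up to additive constants)
#' and their gradients; they are the quantities the accept-reject steps and
#' the optional gradient-informed proposals use, and they are kept exposed so
#' they can be checked against the joint posterior and against finite
#' differences.
#'
#' `log_conditional_alpha` is
#' \eqn{\sum_i [y_i\eta_i - \log(1+e^{\eta_i})] - \alpha^2/(2\sigma^2_\alpha)}
#' with \eqn{\eta} evaluated at the substituted `alpha`; `grad_alpha` is
#' \eqn{\sum_i (y_i - \sigma(\eta_i)) - \alpha/\sigma^2_\alpha}. The beta and
#' u versions are analogous, with the u conditional summing only over the
#' patients of center `j`.
#'
#' @param alpha,beta,u_j the value at which the block's conditional is
#'   evaluated; all other blocks are taken from `state`.
#' @param j center index in `1..J`.
#' @param state a [param_state] supplying the conditioning values.
#' @param data a [cohort_data].
#' @param prior an [mwg_prior].
#' @return Scalar log density (up to a constant) or gradient; `grad_beta`
#'   returns a length-p vector.
#' @name full_conditionals
NULL

#' @rdname full_conditionals
#' @export
log_conditional_alpha <- function(alpha, state, data, prior) {
  s <- state
  s$alpha <- alpha
  bernoulli_loglik(data$y, linear_predictor(s, data)) -
    alpha^2 / (2 * prior$sigma2_alpha)
}

#' @rdname full_conditionals
#' @export
grad_alpha <- function(state, data, prior) {
  eta <- linear_predictor(state, data)
  sum(data$y - logistic(eta)) - state$alpha / prior$sigma2_alpha
}

#' @rdname full_conditionals
#' @export
log_conditional_beta <- function(beta, state, data, prior) {
  if (length(beta) != data$n_covariates)
    stop("beta length does not match design matrix", call. = FALSE)
  s <- state
  s$beta <- beta
  eta <- linear_predictor(s, data)
  v <- beta_prior_var(prior, data$n_covariates)
  xb <- if (data$n_covariates > 0) drop(data$X %*% beta) else numeric(data$n_patients)
  sum(data$y * xb) - sum(log1pexp(eta)) - 0.5 * sum(beta^2 / v)
}

#' @rdname full_conditionals
#' @export
grad_beta <- function(state, data, prior) {
  eta <- linear_predictor(state, data)
  v <- beta_prior_var(prior, data$n_covariates)
  drop(crossprod(data$X, data$y - logistic(eta))) - state$beta / v
}

#' @rdname full_conditionals
#' @export
log_conditional_u <- function(j, u_j, state, data, prior) {
  if (j < 1 || j > data$n_centers) stop("invalid center index", call. = FALSE)
  s <- state
  s$u[j] <- u_j
  idx <- which(data$center_index == j)
  eta <- linear_predictor(s, data)[idx]
  bernoulli_loglik(data$y[idx], eta) - u_j^2 / (2 * state$sigma2_u)
}

#' @rdname full_conditionals
#' @export
grad_u <- function(j, state, data, prior) {
  if (j < 1 || j > data$n_centers) stop("invalid center index", call. = FALSE)
  idx <- which(data$center_index == j)
  eta <- linear_predictor(state, data)[idx]
  sum(data$y[idx] - logistic(eta)) - state$u[j] / state$sigma2_u
}

#' Conjugate Inverse-Gamma full conditional of the between-center variance
#'
#' Given the center effects, \eqn{\sigma^2_u \mid u \sim IG(a_0 + J/2,\;
#' b_0 + \tfrac12 \sum_j u_j^2)} — the one block of the model with a
#' closed-form Gibbs update.
#'
#' @param u vector of center random intercepts.
#' @param a0,b0 Inverse-Gamma prior shape and rate.
#' @return A list with elements `shape` and `rate`.
#' @export
ig_full_conditional_params <- function(u, a0 = 1, b0 = 1) {
  if (length(u) == 0) stop("u must be non-empty", call. = FALSE)
  stopifnot(a0 > 0, b0 > 0)
  list(shape = a0 + length(u) / 2, rate = b0 + 0.5 * sum(u^2))
}

#' Log joint posterior density (up to a constant)
#'
#' Log-likelihood plus log-priors for all blocks, including the
#' \eqn{-(J/2)\log\sigma^2_u} normalizer of the center-effect prior and the
#' Inverse-Gamma prior for \eqn{\sigma^2_u}. Used throughout the test suite
#' as the oracle against which every block conditional is checked.
#'
#' @inheritParams full_conditionals
#' @return Scalar log density, up to a state-independent constant.
#' @export
log_joint_posterior <- function(state, data, prior) {
  if (state$sigma2_u <= 0) stop("sigma2_u must be > 0", call. = FALSE)
  ll <- bernoulli_loglik(data$y, linear_predictor(state, data))
  lp <- -state$alpha^2 / (2 * prior$sigma2_alpha)
  if (data$n_covariates > 0) {
    v <- beta_prior_var(prior, data$n_covariates)
    lp <- lp - 0.5 * sum(state$beta^2 / v)
  }
  if (data$n_centers > 0) {
    J <- data$n_centers
    lp <- lp - sum(state$u^2) / (2 * state$sigma2_u) - (J / 2) * log(state$sigma2_u)
    lp <- lp - (prior$a0 + 1) * log(state$sigma2_u) - prior$b0 / state$sigma2_u
  }
  ll + lp
}
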