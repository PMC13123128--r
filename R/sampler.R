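#' Sampler configuration
#'
#' Settings for the Metropolis-Hastings-within-Gibbs run. Defaults mirror the
#' published analysis protocol: 20,000 iterations per chain, 2,000 burn-in,
#' no thinning, three chains, and burn-in-only proposal adaptation targeting
#' per-block acceptance rates between 20% and 40%.
#'
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations (must be `< n_iter`).
#' @param thin thinning interval applied after burn-in removal; the retained
#'   count per chain is `floor((n_iter - burn_in)/thin)`.
#' @param n_chains number of independent chains (disjoint RNG substreams,
#'   overdispersed initial values).
#' @param proposal_sd initial random-walk proposal standard deviation:
#'   `NULL` (default) starts each block at the pilot-style
#'   inverse-information scale for its own data slice; otherwise a scalar
#'   (used for every block) or a list with elements `alpha`, `beta`
#'   (length p or scalar) and `u` (length J or scalar).
#' @param adapt adapt proposal scales during burn-in only; the kernel is
#'   frozen afterwards so retained draws come from a fixed transition kernel.
#' @param adapt_window iterations per adaptation window.
#' @param target_accept length-2 acceptance-rate window; scales move up by
#'   10% above the window and down by 10% below it.
#' @param kernel `"rw"` for random-walk proposals (the default, matching the
#'   published decision rules) or `"mala"` for gradient-informed
#'   Langevin-style proposals with the asymmetric-proposal correction.
#' @return A list of class `"mwg_control"`.
#' @export
mwg_control <- function(n_iter = 20000, burn_in = 2000, thin = 1,
                        n_chains = 3, proposal_sd = NULL, adapt = TRUE,
                        adapt_window = 100, target_accept = c(0.20, 0.40),
                        kernel = c("rw", "mala")) {
  kernel <- match.arg(kernel)
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1,
            length(target_accept) == 2, target_accept[1] < target_accept[2])
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 proposal_sd = proposal_sd, adapt = isTRUE(adapt),
                 adapt_window = as.integer(adapt_window),
                 target_accept = as.numeric(target_accept), kernel = kernel),
            class = "mwg_control")
}

#' Retained draws per chain implied by a sampler configuration
#'
#' @param n_iter,burn_in,thin see [mwg_control()].
#' @return `floor((n_iter - burn_in) / thin)`.
#' @export
retained_per_chain <- function(n_iter, burn_in, thin = 1) {
  as.integer(floor((n_iter - burn_in) / thin))
}

#' Metropolis-Hastings accept-reject decision
#'
#' Accepts with probability \eqn{\min(1, e^{\Delta})} where \eqn{\Delta} is
#' the difference of log target densities (plus any proposal-asymmetry
#' correction, already folded into the arguments). Consumes exactly one
#' uniform random number per call so that sampler runs are reproducible
#' draw-for-draw.
#'
#' @param log_target_proposed,log_target_current log target density at the
#'   proposed and current points; a proposal with `-Inf` log density is never
#'   accepted, and a finite proposal is always accepted from a `-Inf`
#'   current point.
#' @return `TRUE` to accept.
#' @export
mh_accept <- function(log_target_proposed, log_target_current) {
  lu <- log(stats::runif(1))
  if (log_target_proposed == -Inf) return(FALSE)
  if (log_target_current == -Inf) return(TRUE)
  delta <- log_target_proposed - log_target_current
  lu < delta
}

# Gaussian log-density kernel used by the MALA correction (constants cancel)
.lq <- function(x, mean, tau) -(x - mean)^2 / (2 * tau^2)

#' Single-block Metropolis updates and the conjugate variance draw
#'
#' Reference implementations of the four block updates the sampler cycles
#' through. Each Metropolis update draws one Gaussian proposal and one
#' uniform; rejected proposals leave the state untouched. `update_beta`
#' sweeps the coordinates in ascending order, each accepted or rejected
#' against the full conditional at the current values of the other
#' coordinates; `update_u` evaluates the acceptance ratio with the patients
#' of the proposed center only (plus its Gaussian prior term).
#' `update_sigma2_u` is an exact Gibbs draw from the Inverse-Gamma full
#' conditional and is always "accepted".
#'
#' These R functions define the sampler's semantics; [run_chain()] runs the
#' same cycle (identically, draw-for-draw) through a compiled loop.
#'
#' @param state a [param_state].
#' @param data a [cohort_data].
#' @param prior an [mwg_prior].
#' @param tau_alpha,tau_beta,tau_u proposal standard deviations (vectors for
#'   beta/u, recycled if scalar).
#' @param kernel `"rw"` or `"mala"`.
#' @return `update_alpha`: `list(state, accepted)`; `update_beta`/`update_u`:
#'   `list(state, accepted)` with a logical vector per coordinate;
#'   `update_sigma2_u`: the new state.
#' @name block_updates
NULL

#' @rdname block_updates
#' @export
update_alpha <- function(state, data, prior, tau_alpha, kernel = "rw") {
  cur <- state$alpha
  if (kernel == "mala") {
    g <- grad_alpha(state, data, prior)
    m <- cur + 0.5 * tau_alpha^2 * g
    prop <- stats::rnorm(1, m, tau_alpha)
    sp <- state; sp$alpha <- prop
    gp <- grad_alpha(sp, data, prior)
    corr <- .lq(cur, prop + 0.5 * tau_alpha^2 * gp, tau_alpha) -
      .lq(prop, m, tau_alpha)
  } else {
    prop <- stats::rnorm(1, cur, tau_alpha)
    corr <- 0
  }
  lr_new <- log_conditional_alpha(prop, state, data, prior) + corr
  lr_old <- log_conditional_alpha(cur, state, data, prior)
  acc <- mh_accept(lr_new, lr_old)
  if (acc) state$alpha <- prop
  list(state = state, accepted = acc)
}

#' @rdname block_updates
#' @export
update_beta <- function(state, data, prior, tau_beta, kernel = "rw") {
  p <- data$n_covariates
  tau_beta <- rep_len(tau_beta, p)
  acc <- logical(p)
  for (k in seq_len(p)) {
    cur <- state$beta[k]
    if (kernel == "mala") {
      g <- grad_beta(state, data, prior)[k]
      m <- cur + 0.5 * tau_beta[k]^2 * g
      prop <- stats::rnorm(1, m, tau_beta[k])
      sp <- state; sp$beta[k] <- prop
      gp <- grad_beta(sp, data, prior)[k]
      corr <- .lq(cur, prop + 0.5 * tau_beta[k]^2 * gp, tau_beta[k]) -
        .lq(prop, m, tau_beta[k])
    } else {
      prop <- stats::rnorm(1, cur, tau_beta[k])
      corr <- 0
    }
    bp <- state$beta; bp[k] <- prop
    lr_new <- log_conditional_beta(bp, state, data, prior) + corr
    lr_old <- log_conditional_beta(state$beta, state, data, prior)
    acc[k] <- mh_accept(lr_new, lr_old)
    if (acc[k]) state$beta[k] <- prop
  }
  list(state = state, accepted = acc)
}

#' @rdname block_updates
#' @export
update_u <- function(state, data, prior, tau_u, kernel = "rw") {
  J <- data$n_centers
  tau_u <- rep_len(tau_u, J)
  acc <- logical(J)
  for (j in seq_len(J)) {
    cur <- state$u[j]
    if (kernel == "mala") {
      g <- grad_u(j, state, data, prior)
      m <- cur + 0.5 * tau_u[j]^2 * g
      prop <- stats::rnorm(1, m, tau_u[j])
      sp <- state; sp$u[j] <- prop
      gp <- grad_u(j, sp, data, prior)
      corr <- .lq(cur, prop + 0.5 * tau_u[j]^2 * gp, tau_u[j]) -
        .lq(prop, m, tau_u[j])
    } else {
      prop <- stats::rnorm(1, cur, tau_u[j])
      corr <- 0
    }
    lr_new <- log_conditional_u(j, prop, state, data, prior) + corr
    lr_old <- log_conditional_u(j, cur, state, data, prior)
    acc[j] <- mh_accept(lr_new, lr_old)
    if (acc[j]) state$u[j] <- prop
  }
  list(state = state, accepted = acc)
}

#' @rdname block_updates
#' @export
update_sigma2_u <- function(state, prior) {
  par <- ig_full_conditional_params(state$u, prior$a0, prior$b0)
  state$sigma2_u <- 1 / stats::rgamma(1, shape = par$shape, rate = par$rate)
  state
}

#' Multiplicative proposal-scale adaptation
#'
#' Rescales each block's proposal standard deviation from its acceptance
#' rate over the last adaptation window: 10% up above the target window, 10%
#' down below it, unchanged inside it. Called by the chain loop during
#' burn-in only; after burn-in the kernel is frozen so the retained draws
#' come from a fixed-kernel chain.
#'
#' @param accept_rate acceptance rate(s) over the window.
#' @param tau current proposal SD(s), same length.
#' @param target length-2 target acceptance window.
#' @param factor multiplicative step (default 1.1).
#' @return Updated proposal SD(s).
#' @export
adapt_proposals <- function(accept_rate, tau, target = c(0.20, 0.40),
                            factor = 1.1) {
  stopifnot(length(accept_rate) == length(tau))
  tau * ifelse(accept_rate > target[2], factor,
               ifelse(accept_rate < target[1], 1 / factor, 1))
}

# pilot-style initial proposal scales: the inverse square root of each
# block's approximate Bernoulli information at the pooled event rate, the
# scale a short pilot run would land on; adaptation then refines them
heuristic_proposal_sd <- function(data) {
  w <- mean(data$y) * (1 - mean(data$y))
  w <- max(w, 1e-3)
  sc <- function(info) pmin(2.5, pmax(0.02, 2.4 / sqrt(pmax(info, 1))))
  list(alpha = sc(data$n_patients * w),
       beta = if (data$n_covariates > 0)
         sc(colSums(data$X^2) * w) else numeric(0),
       u = if (data$n_centers > 0)
         sc(tabulate(data$center_index, data$n_centers) * w) else numeric(0))
}

# normalize proposal_sd spec into per-coordinate vectors
expand_proposal_sd <- function(proposal_sd, p, J) {
  if (is.list(proposal_sd)) {
    list(alpha = as.numeric(proposal_sd$alpha %||% 0.1),
         beta = rep_len(as.numeric(proposal_sd$beta %||% 0.1), p),
         u = rep_len(as.numeric(proposal_sd$u %||% 0.1), J))
  } else {
    list(alpha = as.numeric(proposal_sd),
         beta = rep_len(as.numeric(proposal_sd), p),
         u = rep_len(as.numeric(proposal_sd), J))
  }
}

#' Run one MCMC chain
#'
#' Executes the update cycle (intercept, fixed-effect sweep, center-effect
#' sweep, exact variance draw) `n_iter` times, adapting proposal scales
#' during burn-in and retaining every `thin`-th post-burn-in state. Uses the
#' R random number stream, so results are reproducible from the seed set
#' before the call. The `"cpp"` engine is the production path; the `"r"`
#' engine runs the reference updates of [update_alpha()] and friends and
#' consumes the RNG stream identically, draw for draw.
#'
#' @param data a [cohort_data].
#' @param prior an [mwg_prior].
#' @param control an [mwg_control].
#' @param init initial [param_state] (default: zero effects, unit variance,
#'   intercept at the empirical pooled log-odds).
#' @param engine `"cpp"` (compiled) or `"r"` (reference).
#' @return A list with retained draws (`alpha`, `beta`, `u`, `sigma2_u`),
#'   post-burn-in acceptance counts per block, final proposal SDs and the
#'   retained count `S`.
#' @export
run_chain <- function(data, prior, control, init = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  p <- data$n_covariates
  J <- data$n_centers
  if (is.null(init)) init <- default_init(data)
  check_state_dims(init, data)
  lp0 <- log_joint_posterior_safe(init, data, prior)
  if (!is.finite(lp0))
    stop("log posterior is not finite at the initial state; check the data and init",
         call. = FALSE)
  tau <- if (is.null(control$proposal_sd)) heuristic_proposal_sd(data)
         else expand_proposal_sd(control$proposal_sd, p, J)
  if (engine == "cpp") {
    res <- .run_chain_cpp(
      data$y, data$X, data$center_index, J,
      prior$sigma2_alpha, beta_prior_var(prior, p), prior$a0, prior$b0,
      control$n_iter, control$burn_in, control$thin,
      init$alpha, init$beta, init$u, init$sigma2_u,
      tau$alpha, tau$beta, tau$u,
      control$adapt, control$adapt_window,
      control$target_accept[1], control$target_accept[2],
      match(control$kernel, c("rw", "mala")) - 1L)
  } else {
    res <- run_chain_r(data, prior, control, init, tau)
  }
  names(res$accept_beta) <- colnames(data$X)
  names(res$accept_u) <- data$center_labels
  colnames(res$beta) <- colnames(data$X)
  colnames(res$u) <- data$center_labels
  res$n_post <- control$n_iter - control$burn_in
  res
}

# plain-R chain loop; consumes the RNG stream identically to the C++ loop
run_chain_r <- function(data, prior, control, init, tau) {
  p <- data$n_covariates
  J <- data$n_centers
  S <- retained_per_chain(control$n_iter, control$burn_in, control$thin)
  alpha_d <- numeric(S)
  beta_d <- matrix(0, S, p)
  u_d <- matrix(0, S, J)
  s2_d <- numeric(S)
  acc_alpha <- 0L; acc_beta <- integer(p); acc_u <- integer(J)
  win_alpha <- 0L; win_beta <- integer(p); win_u <- integer(J)
  state <- init
  s <- 0L
  for (it in seq_len(control$n_iter)) {
    up <- update_alpha(state, data, prior, tau$alpha, control$kernel)
    state <- up$state
    if (up$accepted) { win_alpha <- win_alpha + 1L
      if (it > control$burn_in) acc_alpha <- acc_alpha + 1L }
    if (p > 0) {
      up <- update_beta(state, data, prior, tau$beta, control$kernel)
      state <- up$state
      win_beta <- win_beta + up$accepted
      if (it > control$burn_in) acc_beta <- acc_beta + up$accepted
    }
    if (J > 0) {
      up <- update_u(state, data, prior, tau$u, control$kernel)
      state <- up$state
      win_u <- win_u + up$accepted
      if (it > control$burn_in) acc_u <- acc_u + up$accepted
      state <- update_sigma2_u(state, prior)
    }
    if (control$adapt && it <= control$burn_in && it %% control$adapt_window == 0) {
      w <- control$adapt_window
      tau$alpha <- adapt_proposals(win_alpha / w, tau$alpha, control$target_accept)
      if (p > 0) tau$beta <- adapt_proposals(win_beta / w, tau$beta, control$target_accept)
      if (J > 0) tau$u <- adapt_proposals(win_u / w, tau$u, control$target_accept)
      win_alpha <- 0L; win_beta <- integer(p); win_u <- integer(J)
    }
    if (it > control$burn_in && (it - control$burn_in) %% control$thin == 0) {
      s <- s + 1L
      alpha_d[s] <- state$alpha
      if (p > 0) beta_d[s, ] <- state$beta
      if (J > 0) u_d[s, ] <- state$u
      s2_d[s] <- state$sigma2_u
    }
  }
  list(alpha = alpha_d, beta = beta_d, u = u_d, sigma2_u = s2_d,
       accept_alpha = acc_alpha, accept_beta = acc_beta, accept_u = acc_u,
       tau_final = tau, S = S)
}

default_init <- function(data) {
  rate <- mean(data$y)
  rate <- min(max(rate, 1 / (data$n_patients + 1)), data$n_patients / (data$n_patients + 1))
  param_state(alpha = stats::qlogis(rate), beta = numeric(data$n_covariates),
              u = numeric(data$n_centers), sigma2_u = 1)
}

check_state_dims <- function(state, data) {
  if (length(state$beta) != data$n_covariates || length(state$u) != data$n_centers)
    stop("initial state dimensions do not match the cohort", call. = FALSE)
  invisible(TRUE)
}

log_joint_posterior_safe <- function(state, data, prior) {
  out <- tryCatch(log_joint_posterior(state, data, prior), error = function(e) NaN)
  out
}

#' Run multiple independent chains
#'
#' Chains use disjoint L'Ecuyer-CMRG random-number substreams derived
#' deterministically from `(seed, chain_id)` and overdispersed initial
#' states: chain 1 starts at the pooled empirical log-odds with zero effects,
#' later chains jitter the intercept and coefficients by N(0, 0.5^2).
#'
#' @inheritParams run_chain
#' @param seed master seed (integer). `NULL` uses the current RNG state to
#'   pick one.
#' @return An object of class `"mwg_draws"`: list of per-chain draw lists,
#'   plus acceptance bookkeeping and the configuration echo.
#' @export
run_chains <- function(data, prior, control, seed = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seed <- as.integer(seed)
  old_kind <- RNGkind()
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = globalenv())
  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    assign(".Random.seed", stream, envir = globalenv())
    init <- default_init(data)
    if (ch > 1) {
      init$alpha <- init$alpha + stats::rnorm(1, 0, 0.5)
      if (data$n_covariates > 0)
        init$beta <- init$beta + stats::rnorm(data$n_covariates, 0, 0.5)
    }
    chains[[ch]] <- run_chain(data, prior, control, init, engine)
    stream <- parallel::nextRNGStream(stream)
  }
  structure(list(chains = chains, control = control, prior = prior,
                 seed = seed, n_chains = control$n_chains,
                 coef_names = colnames(data$X),
                 center_labels = data$center_labels),
            class = "mwg_draws")
}

#' Pool retained draws across chains into a matrix
#'
#' @param x an `"mwg_draws"` object or a fitted [mwg_logit] model.
#' @param ... unused.
#' @return Matrix with one row per retained draw (chains stacked) and named
#'   columns `alpha`, `beta.<name>`, `u.<label>`, `sigma2_u`.
#' @export
pool_draws <- function(x, ...) {
  if (inherits(x, "mwg_logit")) x <- x$draws
  mats <- lapply(x$chains, function(ch) {
    cbind(alpha = ch$alpha,
          if (ncol(ch$beta) > 0) structure(ch$beta, dimnames = list(NULL, paste0("beta.", colnames(ch$beta)))),
          if (ncol(ch$u) > 0) structure(ch$u, dimnames = list(NULL, paste0("u.", colnames(ch$u)))),
          sigma2_u = ch$sigma2_u)
  })
  do.call(rbind, mats)
}
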