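#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (unsplit) PSRF: with \eqn{m} chains of length \eqn{n}, let
#' \eqn{W} be the mean within-chain variance and \eqn{B/n} the variance of
#' the chain means; then \eqn{\hat V = \frac{n-1}{n} W + \frac{1}{n} B} and
#' \eqn{\mathrm{PSRF} = \sqrt{\hat V / W}}. Values near 1 indicate the
#' chains have mixed into a common distribution. `split = TRUE` halves each
#' chain first (the split-chain variant, more sensitive to trends).
#'
#' @param chains list of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.
#' @param split split each chain in half before computing.
#' @return The PSRF (scalar, >= 1 up to numerical tolerance).
#' @export
psrf <- function(chains, split = FALSE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2) stop("PSRF requires at least 2 chains", call. = FALSE)
  n0 <- unique(lengths(chains))
  if (length(n0) != 1) stop("chains must have equal length", call. = FALSE)
  if (n0 < 10) stop("chains too short for PSRF", call. = FALSE)
  if (split) {
    half <- floor(n0 / 2)
    chains <- unlist(lapply(chains, function(x)
      list(x[seq_len(half)], x[half + seq_len(half)])), recursive = FALSE)
  }
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  if (W == 0) stop("PSRF undefined: zero within-chain variance", call. = FALSE)
  B <- n * stats::var(means)
  Vhat <- (n - 1) / n * W + B / n
  sqrt(Vhat / W)
}

#' Effective sample size via Geyer's initial positive sequence
#'
#' \eqn{\mathrm{ESS} = S / (1 + 2\sum_{t\ge 1}\rho_t)} with the
#' autocorrelation sum truncated at the last lag pair whose sum
#' \eqn{\rho_{2k} + \rho_{2k+1}} is positive (initial positive sequence);
#' the result is clipped to \eqn{(0, S]}.
#'
#' @param draws numeric vector of MCMC draws (a single chain or pooled).
#' @return The effective sample size.
#' @export
ess <- function(draws) {
  S <- length(draws)
  if (S < 10) stop("too few draws for ESS", call. = FALSE)
  if (stats::var(draws) == 0) stop("ESS undefined: zero variance", call. = FALSE)
  # FFT-based autocorrelation (all lags, O(S log S))
  xc <- draws - mean(draws)
  m <- stats::nextn(2 * S, 2)
  f <- stats::fft(c(xc, rep(0, m - S)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[seq_len(S)]
  rho <- ac / ac[1]
  # rho[1] is lag 0; pair consecutive lags (1,2), (3,4), ...
  tau <- 1
  t <- 2
  while (t + 1 <= length(rho)) {
    g <- rho[t] + rho[t + 1]
    if (g <= 0) break
    tau <- tau + 2 * g
    t <- t + 2
  }
  min(max(S / tau, .Machine$double.eps), S)
}

#' Convergence diagnostics table for a fitted model
#'
#' PSRF across chains and ESS (summed over chains) for every retained
#' parameter. The published stability criterion for this model family is
#' PSRF near 1.0 and ESS above 200.
#'
#' @param fit a fitted [mwg_logit] (needs >= 2 chains for PSRF).
#' @param split use split-chain PSRF.
#' @return Data frame with columns `psrf` and `ess`, one row per parameter.
#' @export
convergence_table <- function(fit, split = FALSE) {
  chains <- fit$draws$chains
  mats <- lapply(chains, function(ch)
    cbind(alpha = ch$alpha,
          if (ncol(ch$beta) > 0) structure(ch$beta, dimnames = list(NULL, paste0("beta.", colnames(ch$beta)))),
          if (ncol(ch$u) > 0) structure(ch$u, dimnames = list(NULL, paste0("u.", colnames(ch$u)))),
          sigma2_u = ch$sigma2_u))
  pn <- colnames(mats[[1]])
  res <- data.frame(psrf = rep(NA_real_, length(pn)),
                    ess = rep(NA_real_, length(pn)), row.names = pn)
  for (i in seq_along(pn)) {
    per_chain <- lapply(mats, function(m) m[, i])
    res$psrf[i] <- tryCatch(psrf(per_chain, split = split),
                            error = function(e) NA_real_)
    res$ess[i] <- tryCatch(sum(vapply(per_chain, ess, numeric(1))),
                           error = function(e) NA_real_)
  }
  res
}

#' Posterior summary table for a draws matrix
#'
#' @param draws matrix of draws (rows) by parameters (columns).
#' @param exponentiate append columns `or`, `or_lower`, `or_upper`: the
#'   exponential of the unrounded `mean`, `q2.5` and `q97.5` columns, giving
#'   odds ratios (or SIRs) with credible bounds on the ratio scale.
#' @return Data frame with columns `mean`, `sd`, `q2.5`, `q25`, `q50`,
#'   `q75`, `q97.5` (and the exponentiated columns if requested).
#' @export
posterior_summary <- function(draws, exponentiate = FALSE) {
  draws <- as.matrix(draws)
  qs <- t(apply(draws, 2, stats::quantile, probs = c(.025, .25, .5, .75, .975)))
  out <- data.frame(mean = colMeans(draws),
                    sd = apply(draws, 2, stats::sd),
                    q2.5 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3],
                    q75 = qs[, 4], q97.5 = qs[, 5],
                    row.names = colnames(draws))
  if (exponentiate) {
    out$or <- exp(out$mean)
    out$or_lower <- exp(out$q2.5)
    out$or_upper <- exp(out$q97.5)
  }
  out
}

#' ROC AUC by the Mann-Whitney formulation
#'
#' Probability that a randomly chosen event outranks a randomly chosen
#' non-event, with ties resolved by midranks — equivalent to the
#' trapezoidal area under the ROC curve.
#'
#' @param scores numeric predictions.
#' @param labels binary outcomes (0/1).
#' @return AUC in `[0, 1]`.
#' @export
auc_mannwhitney <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: outcome has a single class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Posterior predictive ROC/AUC check
#'
#' For each retained posterior draw, computes per-patient event
#' probabilities and the AUC of those probabilities against the observed
#' outcomes; reports the 2.5/50/97.5% quantiles of the per-draw AUC plus the
#' AUC of the draw-averaged probabilities. An AUC well above 0.5 indicates
#' the fitted case-mix model discriminates events from non-events.
#'
#' @param fit a fitted [mwg_logit].
#' @param max_draws cap on the number of posterior draws scored (a thinned
#'   subset is used above the cap, keeping the check affordable).
#' @return List with `auc_quantiles` (named vector) and `auc_mean_prob`.
#' @export
posterior_predictive_auc <- function(fit, max_draws = 2000) {
  pr <- predict_probs(fit, max_draws = max_draws)
  y <- fit$cohort$y
  if (length(unique(y)) < 2)
    stop("AUC undefined: outcome has a single class", call. = FALSE)
  aucs <- apply(pr, 1, auc_mannwhitney, labels = y)
  list(auc_quantiles = stats::quantile(aucs, c(.025, .5, .975)),
       auc_mean_prob = auc_mannwhitney(colMeans(pr), y))
}
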