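# per-draw linear predictors for a cohort, chunked over draws
predict_eta <- function(fit, cohort = fit$cohort, max_draws = Inf) {
  pooled <- pool_draws(fit)
  S <- nrow(pooled)
  keep <- if (S > max_draws) round(seq(1, S, length.out = max_draws)) else seq_len(S)
  alpha <- pooled[keep, "alpha"]
  bcols <- grep("^beta\\.", colnames(pooled), value = TRUE)
  ucols <- grep("^u\\.", colnames(pooled), value = TRUE)
  eta <- matrix(alpha, nrow = length(keep), ncol = cohort$n_patients)
  if (length(bcols)) {
    B <- pooled[keep, bcols, drop = FALSE]
    eta <- eta + B %*% t(cohort$X)
  }
  if (length(ucols)) {
    U <- pooled[keep, ucols, drop = FALSE]
    eta <- eta + U[, cohort$center_index, drop = FALSE]
  }
  eta
}

#' Per-draw posterior predictive probabilities
#'
#' For each retained posterior draw \eqn{s}, computes
#' \eqn{p_i^{(s)} = \sigma(\alpha^{(s)} + x_i^\top\beta^{(s)} +
#' u_{j[i]}^{(s)})} for every patient.
#'
#' @param fit a fitted [mwg_logit].
#' @param cohort a [cohort_data] (defaults to the training cohort; its
#'   centers must be the fitted ones).
#' @param max_draws optional cap; above it an evenly thinned subset of draws
#'   is used. The full draw-by-patient matrix can be large — about
#'   `8 * S * n` bytes.
#' @return Matrix with one row per draw and one column per patient.
#' @export
predict_probs <- function(fit, cohort = fit$cohort, max_draws = Inf) {
  if (cohort$n_centers > 0 &&
      !all(cohort$center_labels %in% fit$cohort$center_labels))
    stop("cohort contains centers absent from the fitted draws", call. = FALSE)
  stats::plogis(predict_eta(fit, cohort, max_draws))
}

#' Per-center expected event counts
#'
#' \eqn{E_j^{(s)} = \sum_{i: j[i]=j} p_i^{(s)}} for each posterior draw, and
#' \eqn{E_j} the average over draws — the model-based expected count used as
#' the denominator of the standardized incidence ratio.
#'
#' @param prob_draws draws-by-patients probability matrix
#'   (from [predict_probs()]).
#' @param center_index per-patient center assignment in `1..J`.
#' @return List with `E_draws` (draws x J matrix) and `E` (length-J vector).
#' @export
expected_counts <- function(prob_draws, center_index) {
  J <- max(center_index)
  E_draws <- t(rowsum(t(prob_draws), group = center_index))
  colnames(E_draws) <- NULL
  if (ncol(E_draws) != J) stop("centers with no patients", call. = FALSE)
  list(E_draws = E_draws, E = colMeans(E_draws))
}

#' Standardized incidence ratio with zero-count protection
#'
#' \eqn{\mathrm{SIR}_j = (O_j + \epsilon)/(E_j + \epsilon)} and its log. The
#' small \eqn{\epsilon} (default `1e-6`) is applied to numerator and
#' denominator alike, so centers with zero observed events get a finite,
#' extremely negative log-SIR while non-zero centers shift only at order
#' \eqn{\epsilon}.
#'
#' @param O observed event count(s).
#' @param E expected count(s).
#' @param eps continuity constant.
#' @return List with `sir` and `log_sir`.
#' @export
sir <- function(O, E, eps = 1e-6) {
  if (any(O < 0) || any(E < 0) || eps <= 0)
    stop("counts and eps must be non-negative", call. = FALSE)
  s <- (O + eps) / (E + eps)
  list(sir = s, log_sir = log(s))
}

#' Credible interval for a center's SIR
#'
#' Empirical quantiles of the per-draw ratios
#' \eqn{r^{(s)} = (O_j+\epsilon)/(E_j^{(s)}+\epsilon)}; log-scale bounds are
#' the logs of the same quantiles (the transform is monotone).
#'
#' @param O observed count for the center.
#' @param E_draws per-draw expected counts for the center.
#' @param eps continuity constant.
#' @param levels quantile levels.
#' @return List with `sir` and `log_sir` bound vectors.
#' @export
sir_credible_interval <- function(O, E_draws, eps = 1e-6,
                                  levels = c(0.025, 0.975)) {
  r <- (O + eps) / (E_draws + eps)
  q <- stats::quantile(r, levels)
  list(sir = q, log_sir = log(q))
}

#' Posterior variance of a center's log-SIR
#'
#' The default (`"mcmc"`) estimator is the sample variance of the per-draw
#' log ratios \eqn{\log((O_j+\epsilon)/(E_j^{(s)}+\epsilon))}: the observed
#' count is a fixed constant, so all its variance and covariance
#' contributions vanish and the posterior uncertainty in \eqn{E_j} carries
#' the whole variance. `"delta"` gives the classical Poisson/delta-method
#' approximation \eqn{1/O_j + \mathrm{Var}(E_j)/\bar E_j^2} for comparison.
#'
#' @inheritParams sir_credible_interval
#' @param method `"mcmc"` (default) or `"delta"`.
#' @return Scalar variance.
#' @export
var_log_sir <- function(O, E_draws, eps = 1e-6, method = c("mcmc", "delta")) {
  method <- match.arg(method)
  if (method == "mcmc") {
    stats::var(log((O + eps) / (E_draws + eps)))
  } else {
    1 / (O + eps) + stats::var(E_draws) / mean(E_draws)^2
  }
}

#' Conventional funnel-plot control limits
#'
#' \eqn{\mu \pm z_{1-\alpha/2}\,\sigma_j} on the log-SIR scale, where
#' \eqn{\mu} is the benchmark (0 for log-SIR) and \eqn{\sigma_j} the
#' center's log-SIR standard deviation.
#'
#' @param sigma_j per-center standard deviation(s) of log-SIR.
#' @param alpha_level two-sided significance level (0.05 gives z = 1.959964).
#' @param mu benchmark value.
#' @return Data frame with columns `lower` and `upper`.
#' @export
funnel_limits <- function(sigma_j, alpha_level = 0.05, mu = 0) {
  if (any(sigma_j <= 0)) stop("sigma_j must be positive", call. = FALSE)
  stopifnot(alpha_level > 0, alpha_level < 1)
  z <- stats::qnorm(1 - alpha_level / 2)
  data.frame(lower = mu - z * sigma_j, upper = mu + z * sigma_j)
}

#' False-discovery-rate adjusted funnel limits
#'
#' Benjamini-Hochberg step-up on the per-center two-sided p-values
#' \eqn{p_j = 2\Phi(-|\log \mathrm{SIR}_j|/\sigma_j)}: find the largest
#' \eqn{k} with \eqn{p_{(k)} \le (k/m)q}; the FDR-adjusted critical value is
#' \eqn{z_{\mathrm{FDR}} = \Phi^{-1}(1 - p_{(k)}/2)} and each center's
#' limits are \eqn{\pm z_{\mathrm{FDR}}\,\sigma_j}. When the step-up rejects
#' nothing, no center is flagged, `z_fdr` falls back to the conventional
#' \eqn{z_{1-\alpha/2}} and `no_signals` is set.
#'
#' @param log_sirs per-center log-SIR values.
#' @param sigmas per-center log-SIR standard deviations (positive).
#' @param q FDR level.
#' @param alpha_level fallback conventional level when nothing is rejected.
#' @return List with `z_fdr`, `limits` (data frame `lower`/`upper` per
#'   center), `p_values`, `k` (number of BH rejections), `no_signals`.
#' @export
fdr_adjusted_limits <- function(log_sirs, sigmas, q = 0.05,
                                alpha_level = 0.05) {
  m <- length(log_sirs)
  stopifnot(length(sigmas) == m, m >= 1, q > 0, q < 1)
  if (any(sigmas <= 0)) stop("sigmas must be positive", call. = FALSE)
  p <- 2 * stats::pnorm(-abs(log_sirs) / sigmas)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) / m * q)
  if (length(ok) == 0) {
    z <- stats::qnorm(1 - alpha_level / 2)
    k <- 0L
    no_signals <- TRUE
  } else {
    k <- max(ok)
    # upper-tail form keeps full precision for astronomically significant
    # centers (e.g. zero-event centers with p ~ 1e-90); the floor guards
    # against outright underflow to 0
    z <- stats::qnorm(max(ps[k], 1e-300) / 2, lower.tail = FALSE)
    no_signals <- FALSE
  }
  list(z_fdr = z,
       limits = data.frame(lower = -z * sigmas, upper = z * sigmas),
       p_values = p, k = k, no_signals = no_signals)
}

#' Classify centers against credible intervals and funnel limits
#'
#' Credible-interval rule: `above` if the lower 2.5% log-SIR bound exceeds
#' 0, `below` if the upper 97.5% bound is under 0, otherwise `consistent`.
#' Funnel rule: `above`/`below` when the point log-SIR falls strictly
#' outside the center's limits (a point exactly on a limit counts as
#' within — conservative flagging), otherwise `consistent`.
#'
#' @param log_sir point log-SIR per center.
#' @param cri_lower,cri_upper credible bounds on the log scale.
#' @param limits data frame with `lower`/`upper` per center (conventional or
#'   FDR-adjusted).
#' @return Data frame with `cri_class` and (if limits given) `funnel_class`.
#' @export
classify_centers <- function(log_sir, cri_lower, cri_upper, limits = NULL) {
  cri <- ifelse(cri_lower > 0, "above",
                ifelse(cri_upper < 0, "below", "consistent"))
  out <- data.frame(cri_class = cri, stringsAsFactors = FALSE)
  if (!is.null(limits)) {
    out$funnel_class <- ifelse(log_sir > limits$upper, "above",
                               ifelse(log_sir < limits$lower, "below",
                                      "consistent"))
  }
  out
}

#' Center performance profiles from a fitted model
#'
#' The full profiling pipeline: per-draw predicted probabilities, per-center
#' expected counts, SIR and log-SIR with credible intervals, posterior
#' log-SIR variances, precision \eqn{1/\sqrt{E_j}}, conventional and
#' FDR-adjusted funnel limits, and classifications under both rules.
#'
#' @param fit a fitted [mwg_logit] with center effects.
#' @param eps continuity constant of the SIR zero-count rule.
#' @param alpha_level conventional funnel limit level.
#' @param fdr_q FDR level for the adjusted limits.
#' @param mu funnel benchmark on the log-SIR scale.
#' @param max_draws cap on draws used for the predictive step.
#' @return A data frame of class `"center_profiles"`, one row per center,
#'   with attributes `fdr` (the [fdr_adjusted_limits()] result), `E_draws`,
#'   `alpha_level`, `mu` and `eps`.
#' @export
center_profiles <- function(fit, eps = 1e-6, alpha_level = 0.05,
                            fdr_q = 0.05, mu = 0, max_draws = Inf) {
  cohort <- fit$cohort
  if (cohort$n_centers == 0)
    stop("the fitted model has no center effects to profile", call. = FALSE)
  pr <- predict_probs(fit, max_draws = max_draws)
  ec <- expected_counts(pr, cohort$center_index)
  O <- as.integer(rowsum(cohort$y, cohort$center_index))
  N <- as.integer(table(cohort$center_index))
  J <- cohort$n_centers
  point <- sir(O, ec$E, eps)
  cri_l <- cri_u <- vlog <- numeric(J)
  for (j in seq_len(J)) {
    ci <- sir_credible_interval(O[j], ec$E_draws[, j], eps)
    cri_l[j] <- ci$log_sir[1]
    cri_u[j] <- ci$log_sir[2]
    vlog[j] <- var_log_sir(O[j], ec$E_draws[, j], eps)
  }
  sigma_j <- sqrt(vlog)
  conv <- funnel_limits(sigma_j, alpha_level, mu)
  fdr <- fdr_adjusted_limits(point$log_sir, sigma_j, q = fdr_q,
                             alpha_level = alpha_level)
  cls_cri <- classify_centers(point$log_sir, cri_l, cri_u, conv)
  cls_fdr <- classify_centers(point$log_sir, cri_l, cri_u, fdr$limits)
  out <- data.frame(
    center = cohort$center_labels,
    N = N, O = O, E = ec$E,
    sir = point$sir, log_sir = point$log_sir,
    log_sir_sd = sigma_j,
    cri_2.5 = cri_l, cri_97.5 = cri_u,
    sir_cri_2.5 = exp(cri_l), sir_cri_97.5 = exp(cri_u),
    var_log_sir = vlog,
    precision = 1 / sqrt(ec$E),
    limit_lower = conv$lower, limit_upper = conv$upper,
    fdr_lower = fdr$limits$lower, fdr_upper = fdr$limits$upper,
    cri_class = cls_cri$cri_class,
    funnel_class = cls_cri$funnel_class,
    fdr_class = cls_fdr$funnel_class,
    stringsAsFactors = FALSE
  )
  attr(out, "fdr") <- fdr
  attr(out, "E_draws") <- ec$E_draws
  attr(out, "alpha_level") <- alpha_level
  attr(out, "mu") <- mu
  attr(out, "eps") <- eps
  class(out) <- c("center_profiles", "data.frame")
  out
}

#' Plot-ready funnel data
#'
#' Per-center points (precision, log-SIR, in/out flags) plus the limit
#' curves evaluated on a precision grid. On the grid the log-SIR standard
#' deviation is taken equal to the precision-axis value \eqn{1/\sqrt{E}},
#' the usual funnel approximation for a log ratio of counts.
#'
#' @param profiles a [center_profiles()] result.
#' @param precision_grid grid of `1/sqrt(E)` values for the limit curves
#'   (default: 100 points spanning the observed precisions).
#' @return List with `centers` (data frame, input order preserved) and
#'   `curves` (data frame with conventional and FDR limit curves).
#' @export
funnel_plot_data <- function(profiles, precision_grid = NULL) {
  if (is.null(precision_grid))
    precision_grid <- seq(min(profiles$precision) * 0.9,
                          max(profiles$precision) * 1.1, length.out = 100)
  alpha_level <- attr(profiles, "alpha_level") %||% 0.05
  mu <- attr(profiles, "mu") %||% 0
  z <- stats::qnorm(1 - alpha_level / 2)
  zf <- attr(profiles, "fdr")$z_fdr %||% z
  curves <- data.frame(precision = precision_grid,
                       lower = mu - z * precision_grid,
                       upper = mu + z * precision_grid,
                       fdr_lower = mu - zf * precision_grid,
                       fdr_upper = mu + zf * precision_grid)
  centers <- data.frame(center = profiles$center,
                        precision = profiles$precision,
                        log_sir = profiles$log_sir,
                        funnel_class = profiles$funnel_class,
                        fdr_class = profiles$fdr_class,
                        stringsAsFactors = FALSE)
  list(centers = centers, curves = curves)
}

#' @export
print.center_profiles <- function(x, digits = 2, ...) {
  cat(sprintf("Center profiles (%d centers; %d flagged by CrI, %d by FDR limits)\n",
              nrow(x), sum(x$cri_class != "consistent"),
              sum(x$fdr_class != "consistent")))
  print(round(
    as.data.frame(x)[, c("N", "O", "E", "log_sir", "log_sir_sd",
                         "cri_2.5", "cri_97.5", "sir")],
    digits), ...)
  invisible(x)
}

#' Funnel plot of center log-SIRs
#'
#' @param x a [center_profiles()] result.
#' @param fdr draw the FDR-adjusted limit curves too.
#' @param ... passed to [graphics::plot()].
#' @export
plot.center_profiles <- function(x, fdr = TRUE, ...) {
  fd <- funnel_plot_data(x)
  ylim <- range(fd$centers$log_sir, fd$curves$lower, fd$curves$upper)
  graphics::plot(fd$centers$precision, fd$centers$log_sir,
                 xlab = expression(1 / sqrt(E[j])), ylab = "log SIR",
                 pch = 19, ylim = ylim,
                 col = ifelse(fd$centers$funnel_class == "consistent", 1, 2),
                 ...)
  graphics::abline(h = attr(x, "mu") %||% 0, lty = 3)
  graphics::lines(fd$curves$precision, fd$curves$lower, lty = 2)
  graphics::lines(fd$curves$precision, fd$curves$upper, lty = 2)
  if (fdr) {
    graphics::lines(fd$curves$precision, fd$curves$fdr_lower, lty = 4, col = 4)
    graphics::lines(fd$curves$precision, fd$curves$fdr_upper, lty = 4, col = 4)
  }
  invisible(x)
}
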