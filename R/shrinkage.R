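#' Empirical logit of a center's event rate
#'
#' \eqn{\log\big((O_j + c)/(N_j - O_j + c)\big)} with the Haldane-Anscombe
#' continuity correction \eqn{c = 0.5}, which keeps the value finite when a
#' center has zero or all events.
#'
#' @param O observed event count(s), `0 <= O <= N`.
#' @param N patient count(s), positive.
#' @param correction continuity constant added to both cells.
#' @return Empirical logit(s).
#' @export
empirical_logit <- function(O, N, correction = 0.5) {
  if (any(N <= 0)) stop("N must be positive", call. = FALSE)
  if (any(O < 0) || any(O > N)) stop("O must lie in [0, N]", call. = FALSE)
  log((O + correction) / (N - O + correction))
}

#' Model-shrunken logit of a center's event rate
#'
#' The hierarchical model's partial-pooling estimate of a center's event
#' rate on the logit scale: \eqn{\mathrm{logit}(E_j / N_j)} with \eqn{E_j}
#' the posterior-mean expected count. Because every per-draw probability is
#' strictly inside (0, 1), the ratio always is too.
#'
#' @param fit a fitted [mwg_logit] with center effects.
#' @param max_draws cap on draws used for the predictive step.
#' @return Named vector of shrunken logits, one per center, with the
#'   per-draw matrix attached as attribute `"draws"`.
#' @export
shrunken_logit <- function(fit, max_draws = Inf) {
  cohort <- fit$cohort
  pr <- predict_probs(fit, max_draws = max_draws)
  ec <- expected_counts(pr, cohort$center_index)
  N <- as.integer(table(cohort$center_index))
  out <- stats::qlogis(ec$E / N)
  names(out) <- cohort$center_labels
  attr(out, "draws") <- stats::qlogis(sweep(ec$E_draws, 2, N, "/"))
  out
}

#' Shrinkage summary: how far centers are pulled toward the group mean
#'
#' Compares each center's empirical logit with its model-shrunken logit.
#' `distance_moved` is the absolute difference; `pct_moved` is the percent
#' of the center's empirical distance from the group-mean logit removed by
#' shrinkage, \eqn{100\,(|e_j - \bar g| - |s_j - \bar g|)/|e_j - \bar g|}
#' (negative when the model pushes a center away from the mean, which can
#' happen for large centers); `volume_category` splits centers into
#' low/medium/high tertiles of patient volume. Small centers are pulled
#' hardest — the hierarchical model's partial pooling at work.
#'
#' @param fit a fitted [mwg_logit] with center effects.
#' @param group_mean `"unweighted"` (default, plain mean of the empirical
#'   logits) or `"precision"` (volume-weighted mean).
#' @param correction continuity correction for the empirical logit.
#' @param max_draws cap on draws used for the predictive step.
#' @return Data frame with one row per center: `center`, `N`, `O`,
#'   `empirical_logit`, `shrunken_logit`, `group_mean_logit`,
#'   `distance_moved`, `pct_moved` (NA for a center sitting exactly on the
#'   group mean) and `volume_category`.
#' @export
shrinkage_table <- function(fit, group_mean = c("unweighted", "precision"),
                            correction = 0.5, max_draws = Inf) {
  group_mean <- match.arg(group_mean)
  cohort <- fit$cohort
  if (cohort$n_centers == 0)
    stop("the fitted model has no center effects", call. = FALSE)
  O <- as.integer(rowsum(cohort$y, cohort$center_index))
  N <- as.integer(table(cohort$center_index))
  emp <- empirical_logit(O, N, correction)
  shr <- as.numeric(shrunken_logit(fit, max_draws = max_draws))
  gm <- if (group_mean == "unweighted") mean(emp)
        else stats::weighted.mean(emp, w = N)
  d_emp <- abs(emp - gm)
  pct <- ifelse(d_emp > 0, 100 * (d_emp - abs(shr - gm)) / d_emp, NA_real_)
  data.frame(center = cohort$center_labels, N = N, O = O,
             empirical_logit = emp, shrunken_logit = shr,
             group_mean_logit = gm,
             distance_moved = abs(emp - shr), pct_moved = pct,
             volume_category = volume_tertiles(N),
             stringsAsFactors = FALSE)
}

# low/medium/high tertiles of center volume; ties broken by input order
volume_tertiles <- function(N) {
  J <- length(N)
  sizes <- diff(round(seq(0, J, length.out = 4)))
  labels <- rep(c("low", "medium", "high"), times = sizes)
  out <- character(J)
  out[order(N, seq_len(J))] <- labels
  factor(out, levels = c("low", "medium", "high"))
}
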