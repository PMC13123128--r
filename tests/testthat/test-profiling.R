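test_that("predictive probabilities match the per-patient loop oracle", {
  co <- tiny_cohort(n = 25, J = 3, p = 2, seed = 1)
  set.seed(2)
  S <- 10
  ff <- fake_fit(alpha = rnorm(S), beta = rnorm(S * 2), u = rnorm(S * 3),
                 cohort = co)
  pr <- predict_probs(ff)
  ch <- ff$draws$chains[[1]]
  for (s in c(1, 5, 10)) for (i in c(1, 13, 25)) {
    eta <- ch$alpha[s] + sum(co$X[i, ] * ch$beta[s, ]) +
      ch$u[s, co$center_index[i]]
    expect_equal(unname(pr[s, i]), unname(plogis(eta)), tolerance = 1e-12)
  }
  # the all-zero draw predicts one half everywhere
  ff0 <- fake_fit(alpha = 0, beta = rep(0, 2), u = rep(0, 3), cohort = co)
  expect_true(all(predict_probs(ff0) == 0.5))
})

test_that("expected counts conserve the patient partition", {
  co <- tiny_cohort(n = 30, J = 3, p = 1, seed = 3)
  pr <- matrix(0.5, nrow = 4, ncol = 30)
  ec <- expected_counts(pr, co$center_index)
  expect_equal(ec$E, as.numeric(table(co$center_index)) / 2)
  set.seed(4)
  pr <- matrix(runif(7 * 30), 7, 30)
  ec <- expected_counts(pr, co$center_index)
  expect_equal(rowSums(ec$E_draws), rowSums(pr), tolerance = 1e-10)
  # brute-force double loop
  for (s in 1:7) for (j in 1:3)
    expect_equal(ec$E_draws[s, j], sum(pr[s, co$center_index == j]),
                 tolerance = 1e-10)
})

test_that("SIR continuity rule is exact, including zero-event centers", {
  r <- sir(2, 4)
  expect_equal(r$sir, 0.5, tolerance = 1e-5)
  expect_equal(r$log_sir, log(0.5), tolerance = 1e-4)
  z <- sir(0, 1)
  expect_equal(z$log_sir, log(1e-6 / (1 + 1e-6)), tolerance = 1e-12)
  expect_equal(round(z$log_sir, 4), -13.8155)
  e <- sir(3, 3)
  expect_equal(e$sir, 1, tolerance = 1e-9)
  expect_equal(e$log_sir, 0, tolerance = 1e-9)
  expect_error(sir(-1, 2), "non-negative")
  expect_equal(exp(sir(0, 7)$log_sir), sir(0, 7)$sir, tolerance = 1e-12)
})

test_that("SIR credible intervals are quantiles of per-draw ratios", {
  expect_equal(unname(sir_credible_interval(3, rep(6, 50))$sir),
               c(0.5, 0.5), tolerance = 1e-5)
  set.seed(5)
  E <- rlnorm(1000, log(5), 0.3)
  ci <- sir_credible_interval(4, E)
  expect_equal(unname(ci$log_sir), unname(log(ci$sir)), tolerance = 1e-14)
  # sort-based type-7 oracle
  r <- sort((4 + 1e-6) / (E + 1e-6))
  type7 <- function(v, p) {
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[pmin(lo + 1, length(v))] - v[lo])
  }
  expect_equal(unname(ci$sir), c(type7(r, 0.025), type7(r, 0.975)),
               tolerance = 1e-12)
})

test_that("log-SIR variance matches the log-normal closed form", {
  expect_equal(var_log_sir(3, rep(6, 100)), 0)
  set.seed(6)
  sigma <- 0.3
  E <- 5 * exp(rnorm(1e5, 0, sigma))
  expect_equal(var_log_sir(4, E), sigma^2, tolerance = 0.03)
  # joint scaling of O and E leaves the ratio variance unchanged
  expect_equal(var_log_sir(4, E), var_log_sir(40, 10 * E), tolerance = 1e-3)
  expect_gt(var_log_sir(4, E, method = "delta"), 0)
})

test_that("funnel limits use the exact normal quantile and scale linearly", {
  fl <- funnel_limits(1, 0.05)
  expect_equal(fl$upper, 1.959964, tolerance = 1e-6)
  expect_equal(fl$lower, -fl$upper)
  expect_equal(funnel_limits(0.1, 0.05)$upper, 0.1959964, tolerance = 1e-6)
  shifted <- funnel_limits(1, 0.05, mu = 0.5)
  expect_equal(shifted$lower, fl$lower + 0.5)
  expect_equal(shifted$upper, fl$upper + 0.5)
  expect_error(funnel_limits(0, 0.05), "positive")
})

test_that("FDR step-up equals the exhaustive-k oracle on random p-vectors", {
  set.seed(7)
  q <- 0.05
  for (trial in 1:1000) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(c(1, 3), 1)  # mix of uniform and signal-rich
    sg <- rep(1, m)
    ls <- -qnorm(p / 2) * sample(c(-1, 1), m, replace = TRUE)
    res <- fdr_adjusted_limits(ls, sg, q = q)
    ps <- sort(2 * pnorm(-abs(ls)))
    k_oracle <- 0
    for (k in seq_len(m)) if (ps[k] <= k / m * q) k_oracle <- k
    expect_identical(res$k, as.integer(k_oracle))
    if (k_oracle > 0) {
      expect_equal(res$z_fdr,
                   qnorm(ps[k_oracle] / 2, lower.tail = FALSE),
                   tolerance = 1e-12)
      # BH rejection-set cross-check
      expect_identical(sum(p.adjust(ps, "BH") <= q), k_oracle)
    } else {
      expect_true(res$no_signals)
      expect_equal(res$z_fdr, qnorm(0.975), tolerance = 1e-12)
    }
  }
})

test_that("FDR limit edge cases follow the documented conventions", {
  one <- fdr_adjusted_limits(1.2, 0.3, q = 0.05)
  expect_equal(one$z_fdr, 1.2 / 0.3, tolerance = 1e-12)
  ex <- fdr_adjusted_limits(c(-qnorm(0.001 / 2), -qnorm(0.2 / 2) * -1, 0.1),
                            c(1, 1, 1), q = 0.05)
  expect_identical(ex$k, 1L)
  expect_equal(ex$z_fdr, qnorm(1 - 0.001 / 2), tolerance = 1e-9)
  none <- fdr_adjusted_limits(c(0, 0, 0), c(1, 1, 1), q = 0.05)
  expect_true(none$no_signals)
})

test_that("center classification follows the credible-interval rule", {
  cls <- classify_centers(c(0.84, -0.16, -0.99),
                          cri_lower = c(0.53, -0.32, -1.30),
                          cri_upper = c(1.16, 0.01, -0.67))
  expect_identical(cls$cri_class, c("above", "consistent", "below"))
  # a point exactly on a funnel limit is within (conservative flagging)
  lim <- data.frame(lower = -1, upper = 1)
  on_limit <- classify_centers(1, -0.5, 1.5, lim)
  expect_identical(on_limit$funnel_class, "consistent")
  outside <- classify_centers(1.0001, -0.5, 1.5, lim)
  expect_identical(outside$funnel_class, "above")
})

test_that("full center profiles satisfy their structural invariants", {
  cs <- cached_small_fit()
  prof <- center_profiles(cs$fit, max_draws = 500)
  expect_identical(prof$center, cs$fit$cohort$center_labels)
  expect_true(all(prof$O <= prof$N))
  expect_true(all(prof$E > 0 & prof$E <= prof$N))
  expect_equal(exp(prof$log_sir), prof$sir, tolerance = 1e-12)
  expect_true(all(is.finite(prof$log_sir)))
  expect_true(all(prof$cri_2.5 <= prof$cri_97.5))
  expect_true(all(prof$limit_upper == -prof$limit_lower))
  expect_true(all(prof$cri_class %in% c("above", "below", "consistent")))
  # forced zero-event centers: finite and flagged below expectation
  zl <- intersect(cs$sim$truth$forced_zero_event, prof$center)
  expect_true(length(zl) >= 1)
  zrow <- prof[prof$center %in% zl, ]
  expect_true(all(zrow$O == 0))
  expect_true(all(is.finite(zrow$log_sir)))
  expect_true(all(zrow$cri_class == "below"))
})

test_that("funnel plot data preserves ordering and symmetry", {
  cs <- cached_small_fit()
  prof <- center_profiles(cs$fit, max_draws = 300)
  fd <- funnel_plot_data(prof)
  expect_identical(fd$centers$center, prof$center)
  expect_equal(fd$curves$lower, -fd$curves$upper, tolerance = 1e-12)
  expect_equal(fd$curves$fdr_lower, -fd$curves$fdr_upper, tolerance = 1e-12)
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(prof); grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})
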