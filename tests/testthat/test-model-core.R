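test_that("logistic is exact at anchor points and overflow-safe", {
  expect_identical(logistic(0), 0.5)
  expect_equal(logistic(40), 1, tolerance = 1e-15)
  expect_equal(logistic(-2.38), 1 / (1 + exp(2.38)), tolerance = 1e-12)
  expect_equal(round(logistic(-2.38), 4), 0.0847)
  expect_true(all(is.finite(logistic(c(-700, -100, 0, 100, 700)))))
  expect_error(logistic(Inf), "non-finite")
  expect_error(logistic(NA_real_), "non-finite")
})

test_that("linear predictor matches a per-patient loop", {
  co <- tiny_cohort(n = 40, J = 4, p = 3, seed = 2)
  st <- random_state(3, 4, seed = 3)
  eta <- linear_predictor(st, co)
  loop <- vapply(seq_len(co$n_patients), function(i)
    st$alpha + sum(co$X[i, ] * st$beta) + st$u[co$center_index[i]],
    numeric(1))
  expect_equal(eta, loop, tolerance = 1e-14)
  # trivial anchors
  st0 <- param_state(0, rep(0, 3), rep(0, 4))
  expect_equal(linear_predictor(st0, co), rep(0, 40))
  co1 <- cohort_data(1L, matrix(1, 1, 1), 1L)
  expect_equal(linear_predictor(param_state(1, 2, -0.5), co1), 2.5)
  expect_error(linear_predictor(param_state(0, numeric(0), rep(0, 4)), co),
               "beta")
})

test_that("bernoulli log-likelihood is stable and matches the product form", {
  expect_equal(bernoulli_loglik(1, 0), log(0.5), tolerance = 1e-12)
  expect_equal(bernoulli_loglik(c(0, 1), c(0, 0)), 2 * log(0.5),
               tolerance = 1e-12)
  set.seed(4)
  y <- rbinom(50, 1, 0.4)
  eta <- rnorm(50, 0, 2)
  oracle <- sum(log(ifelse(y == 1, plogis(eta), 1 - plogis(eta))))
  expect_equal(bernoulli_loglik(y, eta), oracle, tolerance = 1e-10)
  expect_true(is.finite(bernoulli_loglik(c(1, 0), c(700, -700))))
  expect_error(bernoulli_loglik(c(1, 0), 0), "length")
})

test_that("block conditionals are consistent with the joint posterior", {
  prior <- mwg_prior(sigma2_alpha = 4, sigma2_beta = c(2, 5, 3), a0 = 1.5, b0 = 2)
  for (seed in 1:5) {
    co <- tiny_cohort(n = 80, J = 4, p = 3, seed = seed)
    st <- random_state(3, 4, seed = seed + 100)
    st2 <- random_state(3, 4, seed = seed + 200)
    # alpha block
    d_cond <- log_conditional_alpha(st2$alpha, st, co, prior) -
      log_conditional_alpha(st$alpha, st, co, prior)
    sa <- st; sa$alpha <- st2$alpha
    d_joint <- log_joint_posterior(sa, co, prior) -
      log_joint_posterior(st, co, prior)
    expect_equal(d_cond, d_joint, tolerance = 1e-10)
    # beta block
    d_cond <- log_conditional_beta(st2$beta, st, co, prior) -
      log_conditional_beta(st$beta, st, co, prior)
    sb <- st; sb$beta <- st2$beta
    d_joint <- log_joint_posterior(sb, co, prior) -
      log_joint_posterior(st, co, prior)
    expect_equal(d_cond, d_joint, tolerance = 1e-10)
    # u block, one center at a time
    for (j in 1:4) {
      d_cond <- log_conditional_u(j, st2$u[j], st, co, prior) -
        log_conditional_u(j, st$u[j], st, co, prior)
      su <- st; su$u[j] <- st2$u[j]
      d_joint <- log_joint_posterior(su, co, prior) -
        log_joint_posterior(st, co, prior)
      expect_equal(d_cond, d_joint, tolerance = 1e-10)
    }
    # sigma2_u block against the conjugate IG density
    s2a <- st$sigma2_u; s2b <- st2$sigma2_u
    par <- ig_full_conditional_params(st$u, prior$a0, prior$b0)
    ig_logdiff <- (-(par$shape + 1) * log(s2b) - par$rate / s2b) -
      (-(par$shape + 1) * log(s2a) - par$rate / s2a)
    ss <- st; ss$sigma2_u <- s2b
    d_joint <- log_joint_posterior(ss, co, prior) -
      log_joint_posterior(st, co, prior)
    expect_equal(d_joint, ig_logdiff, tolerance = 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  prior <- mwg_prior(sigma2_alpha = 3, sigma2_beta = 2)
  h <- 1e-5
  for (seed in 1:3) {
    co <- tiny_cohort(n = 70, J = 3, p = 2, seed = seed)
    st <- random_state(2, 3, seed = seed + 10)
    fd <- (log_conditional_alpha(st$alpha + h, st, co, prior) -
             log_conditional_alpha(st$alpha - h, st, co, prior)) / (2 * h)
    expect_equal(grad_alpha(st, co, prior), fd, tolerance = 1e-5)
    gb <- grad_beta(st, co, prior)
    for (k in 1:2) {
      bp <- bm <- st$beta
      bp[k] <- bp[k] + h; bm[k] <- bm[k] - h
      fd <- (log_conditional_beta(bp, st, co, prior) -
               log_conditional_beta(bm, st, co, prior)) / (2 * h)
      expect_equal(unname(gb[k]), fd, tolerance = 1e-5)
    }
    for (j in 1:3) {
      fd <- (log_conditional_u(j, st$u[j] + h, st, co, prior) -
               log_conditional_u(j, st$u[j] - h, st, co, prior)) / (2 * h)
      expect_equal(grad_u(j, st, co, prior), fd, tolerance = 1e-5)
    }
  }
})

test_that("gradient vanishes at a grid-searched posterior mode", {
  co <- tiny_cohort(n = 30, J = 0, p = 0, seed = 6, rate = 0.4)
  prior <- mwg_prior(sigma2_alpha = 1)
  grid <- seq(-3, 3, by = 1e-4)
  lc <- vapply(grid, function(a)
    log_conditional_alpha(a, param_state(a), co, prior), numeric(1))
  mode <- grid[which.max(lc)]
  g <- grad_alpha(param_state(mode), co, prior)
  # |gradient| at the grid mode is bounded by curvature * grid spacing
  expect_lt(abs(g), 0.05)
})

test_that("prior-only limits of the alpha conditional behave", {
  co0 <- cohort_data(integer(0), matrix(numeric(0), 0, 0), NULL)
  flat <- mwg_prior(sigma2_alpha = 1e12)
  d <- log_conditional_alpha(2, param_state(), co0, flat) -
    log_conditional_alpha(-2, param_state(), co0, flat)
  expect_equal(d, 0, tolerance = 1e-10)
  unit <- mwg_prior(sigma2_alpha = 1)
  expect_equal(log_conditional_alpha(1.5, param_state(), co0, unit) -
                 log_conditional_alpha(0, param_state(), co0, unit),
               -1.5^2 / 2, tolerance = 1e-12)
})

test_that("inverse-gamma full conditional parameters are exact", {
  expect_equal(ig_full_conditional_params(rep(0, 34), 1, 1),
               list(shape = 18, rate = 1))
  expect_equal(ig_full_conditional_params(c(1, 1), 1, 1),
               list(shape = 2, rate = 2))
  expect_error(ig_full_conditional_params(numeric(0)), "non-empty")
})

test_that("IG conditional matches grid normalization of prior x likelihood", {
  set.seed(8)
  u <- rnorm(3, 0, 0.7)
  a0 <- 1; b0 <- 1
  par <- ig_full_conditional_params(u, a0, b0)
  grid <- seq(0.01, 60, length.out = 20000)
  # brute force: IG(a0,b0) prior density times the N(0, s2) likelihood of u
  raw <- grid^(-(a0 + 1)) * exp(-b0 / grid) *
    vapply(grid, function(s2) prod(dnorm(u, 0, sqrt(s2))), numeric(1))
  raw <- raw / sum(raw)
  ig <- grid^(-(par$shape + 1)) * exp(-par$rate / grid)
  ig <- ig / sum(ig)
  expect_lt(max(abs(raw - ig)), 1e-6)
})

test_that("log joint posterior is stable and validates input", {
  co <- tiny_cohort(n = 50, J = 3, p = 2, seed = 9)
  prior <- mwg_prior()
  for (a in c(-30, 30)) {
    st <- param_state(alpha = a, beta = c(1, -1), u = rep(0.2, 3))
    expect_true(is.finite(log_joint_posterior(st, co, prior)))
  }
  st <- random_state(2, 3, seed = 1)
  st$sigma2_u <- -1
  expect_error(param_state(sigma2_u = -1), "sigma2_u")
  expect_error(log_joint_posterior(st, co, prior), "sigma2_u")
})
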