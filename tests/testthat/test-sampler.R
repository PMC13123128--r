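test_that("MH decision rule has the right acceptance law", {
  set.seed(1)
  expect_true(all(replicate(50, mh_accept(-1, -1))))   # delta = 0
  expect_true(all(replicate(50, mh_accept(5, 2))))     # delta > 0
  expect_false(any(replicate(50, mh_accept(-Inf, -1))))
  expect_true(all(replicate(50, mh_accept(-1, -Inf))))
  set.seed(42)
  acc <- mean(replicate(1e5, mh_accept(log(0.3), 0)))
  expect_equal(acc, 0.3, tolerance = 0.005 / 0.3)
})

test_that("detailed-balance symmetry: swapping states gives reciprocal ratios", {
  co <- tiny_cohort(n = 40, J = 2, p = 1, seed = 3)
  prior <- mwg_prior()
  st <- random_state(1, 2, seed = 5)
  a1 <- 0.7; a2 <- -1.1
  r12 <- log_conditional_alpha(a2, st, co, prior) -
    log_conditional_alpha(a1, st, co, prior)
  r21 <- log_conditional_alpha(a1, st, co, prior) -
    log_conditional_alpha(a2, st, co, prior)
  expect_equal(r12, -r21, tolerance = 1e-12)
})

test_that("compiled and reference engines are draw-for-draw identical", {
  sim <- simulate_cohort(n_centers = 6, total_patients = 400, seed = 3)
  co <- centerprofile:::build_cohort(outcome ~ sex + diabetes + age_group,
                                     sim$data, "center")
  prior <- mwg_prior()
  ctrl <- mwg_control(n_iter = 800, burn_in = 200, n_chains = 1)
  set.seed(42)
  a <- run_chain(co, prior, ctrl, engine = "cpp")
  set.seed(42)
  b <- run_chain(co, prior, ctrl, engine = "r")
  expect_identical(a$alpha, b$alpha)
  expect_identical(a$beta, b$beta)
  expect_identical(a$u, b$u)
  expect_equal(a$sigma2_u, b$sigma2_u, tolerance = 1e-12)
  expect_identical(a$accept_alpha, b$accept_alpha)
  expect_identical(unname(a$accept_beta), unname(b$accept_beta))
  expect_identical(unname(a$accept_u), unname(b$accept_u))
})

test_that("retention bookkeeping is exact", {
  expect_identical(retained_per_chain(20000, 2000, 1), 18000L)
  expect_identical(retained_per_chain(20000, 2000, 10), 1800L)
  co <- tiny_cohort(n = 30, J = 2, p = 1, seed = 1)
  ctrl <- mwg_control(n_iter = 303, burn_in = 51, thin = 7, n_chains = 1)
  set.seed(1)
  r <- run_chain(co, mwg_prior(), ctrl)
  expect_identical(r$S, retained_per_chain(303, 51, 7))
  expect_identical(length(r$alpha), as.integer(r$S))
})

test_that("runs are reproducible and chains are overdispersed and distinct", {
  co <- tiny_cohort(n = 50, J = 3, p = 1, seed = 2)
  ctrl <- mwg_control(n_iter = 300, burn_in = 100, n_chains = 3)
  d1 <- run_chains(co, mwg_prior(), ctrl, seed = 11)
  d2 <- run_chains(co, mwg_prior(), ctrl, seed = 11)
  expect_identical(pool_draws(d1), pool_draws(d2))
  # distinct substreams: chains differ from each other
  expect_false(identical(d1$chains[[1]]$alpha, d1$chains[[2]]$alpha))
  expect_false(identical(d1$chains[[2]]$alpha, d1$chains[[3]]$alpha))
})

test_that("degenerate proposals are always accepted and freeze the chain", {
  co <- tiny_cohort(n = 40, J = 2, p = 1, seed = 4)
  ctrl <- mwg_control(n_iter = 200, burn_in = 50, n_chains = 1,
                      proposal_sd = 1e-12, adapt = FALSE)
  set.seed(2)
  r <- run_chain(co, mwg_prior(), ctrl)
  expect_equal(r$accept_alpha / 150, 1)
  expect_lt(diff(range(r$alpha)), 1e-9)
})

test_that("acceptance counters equal observed state changes", {
  co <- tiny_cohort(n = 60, J = 3, p = 2, seed = 5)
  ctrl <- mwg_control(n_iter = 600, burn_in = 100, n_chains = 1, thin = 1)
  set.seed(3)
  r <- run_chain(co, mwg_prior(), ctrl)
  moves <- sum(diff(r$alpha) != 0)
  expect_true(r$accept_alpha %in% c(moves, moves + 1L))
  for (k in 1:2) {
    moves <- sum(diff(r$beta[, k]) != 0)
    expect_true(r$accept_beta[k] %in% c(moves, moves + 1L))
  }
})

test_that("non-finite initial state is rejected with a clear message", {
  co <- tiny_cohort(n = 30, J = 2, p = 1, seed = 6)
  bad <- param_state(alpha = 1e308 * 10, beta = 0, u = c(0, 0))
  expect_error(run_chain(co, mwg_prior(), mwg_control(n_iter = 100, burn_in = 10),
                         init = bad),
               "not finite at the initial state")
})

test_that("proposal adaptation scales in the documented directions", {
  expect_equal(adapt_proposals(0.30, 0.2), 0.2)
  expect_equal(adapt_proposals(0.50, 0.2), 0.22)
  expect_equal(adapt_proposals(0.10, 0.22), 0.2)
  # sustained full acceptance grows tau geometrically
  tau <- 0.1
  for (i in 1:10) tau <- adapt_proposals(1, tau)
  expect_equal(tau, 0.1 * 1.1^10, tolerance = 1e-12)
})

test_that("sampler marginals match a grid posterior (2-parameter model)", {
  # intercept + one binary covariate, no center effects: the joint posterior
  # is computable by 2-d quadrature
  set.seed(10)
  n <- 60
  x <- rep(c(0, 1), each = n / 2)
  y <- rbinom(n, 1, plogis(-0.5 + 1.0 * x))
  co <- cohort_data(y, matrix(x, ncol = 1, dimnames = list(NULL, "x")), NULL)
  prior <- mwg_prior(sigma2_alpha = 4, sigma2_beta = 4)
  ga <- seq(-3, 2.5, length.out = 301)
  gb <- seq(-2.5, 3.5, length.out = 301)
  lp <- outer(ga, gb, Vectorize(function(a, b)
    sum(y * (a + b * x) - log1p(exp(a + b * x))) -
      a^2 / 8 - b^2 / 8))
  post <- exp(lp - max(lp)); post <- post / sum(post)
  marg_a <- rowSums(post); marg_b <- colSums(post)
  ctrl <- mwg_control(n_iter = 18000, burn_in = 1000, n_chains = 3)
  fitd <- run_chains(co, prior, ctrl, seed = 5)
  pooled <- pool_draws(fitd)
  expect_gte(nrow(pooled), 50000)
  ks_against_grid <- function(draws, grid, mass) {
    cdf <- approxfun(grid, cumsum(mass), yleft = 0, yright = 1)
    max(abs(ecdf(draws)(draws) - cdf(draws)))
  }
  expect_lt(ks_against_grid(pooled[, "alpha"], ga, marg_a), 0.03)
  expect_lt(ks_against_grid(pooled[, "beta.x"], gb, marg_b), 0.03)
})

test_that("gradient-informed kernel targets the same posterior", {
  set.seed(11)
  n <- 50
  y <- rbinom(n, 1, 0.3)
  co <- cohort_data(y, NULL, NULL)
  prior <- mwg_prior(sigma2_alpha = 4)
  ga <- seq(-4, 2, length.out = 2001)
  lp <- vapply(ga, function(a) sum(y * a - log1p(exp(a))) - a^2 / 8, numeric(1))
  post <- exp(lp - max(lp)); post <- post / sum(post)
  ctrl <- mwg_control(n_iter = 12000, burn_in = 1000, n_chains = 2,
                      kernel = "mala")
  d <- run_chains(co, prior, ctrl, seed = 6)
  draws <- pool_draws(d)[, "alpha"]
  cdf <- approxfun(ga, cumsum(post), yleft = 0, yright = 1)
  expect_lt(max(abs(ecdf(draws)(draws) - cdf(draws))), 0.03)
})

test_that("the conjugate variance block reproduces the inverse-gamma law", {
  st <- param_state(u = rep(0, 34))
  prior <- mwg_prior(a0 = 1, b0 = 1)
  set.seed(12)
  draws <- replicate(1e5, update_sigma2_u(st, prior)$sigma2_u)
  expect_true(all(draws > 0))
  expect_equal(mean(draws), 1 / 17, tolerance = 0.002 / (1 / 17))
  ig_cdf <- function(x) pgamma(1 / x, shape = 18, rate = 1, lower.tail = FALSE)
  ks <- suppressWarnings(ks.test(draws, ig_cdf))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("center-restricted acceptance ratio equals the full-joint ratio", {
  co <- tiny_cohort(n = 80, J = 4, p = 2, seed = 13)
  prior <- mwg_prior()
  st <- random_state(2, 4, seed = 14)
  for (j in 1:4) {
    u_new <- st$u[j] + 0.8
    restricted <- log_conditional_u(j, u_new, st, co, prior) -
      log_conditional_u(j, st$u[j], st, co, prior)
    s2 <- st; s2$u[j] <- u_new
    full <- log_joint_posterior(s2, co, prior) -
      log_joint_posterior(st, co, prior)
    expect_equal(restricted, full, tolerance = 1e-10)
  }
})

test_that("post-burn-in acceptance lands in the tuned window on a registry-like cohort", {
  sim <- simulate_cohort(total_patients = 3000, seed = 21)
  co <- centerprofile:::build_cohort(registry_formula, sim$data, "center")
  ctrl <- mwg_control(n_iter = 4000, burn_in = 2000, n_chains = 1)
  set.seed(9)
  r <- run_chain(co, mwg_prior(), ctrl)
  rates <- c(r$accept_alpha, r$accept_beta, r$accept_u) / 2000
  expect_true(all(rates >= 0.15 & rates <= 0.45))
})
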