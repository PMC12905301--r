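# univariate sensitivity -------------------------------------------------

test_that("univariate slope handles exact, degenerate and seeded cases", {
  # exact collinearity
  r <- univariate_sensitivity(c(-2, 0, 2), c(-1, 0, 1), min_n = 3)
  expect_equal(unname(r$coefficients[["x"]]), 2)
  expect_equal(r$r, 1)
  expect_equal(unname(r$p_value[["x"]]), 0)

  # constant response
  rc <- univariate_sensitivity(rep(5, 10), rnorm(10), min_n = 3)
  expect_equal(unname(rc$coefficients[["x"]]), 0)
  expect_equal(rc$r, 0)

  # zero-variance regressor or too few samples -> missing result
  expect_false(univariate_sensitivity(rnorm(10), rep(1, 10), min_n = 3)$ok)
  expect_false(univariate_sensitivity(rnorm(5), rnorm(5), min_n = 30)$ok)

  # seeded pair against the closed-form slope and t-distribution oracle
  set.seed(200)
  x <- rnorm(200)
  y <- 0.4 * x + rnorm(200)
  r2 <- univariate_sensitivity(y, x, min_n = 30)
  slope_o <- cov(x, y) / var(x)
  expect_equal(unname(r2$coefficients[["x"]]), slope_o, tolerance = 1e-12)
  o <- oracle_ols(y, cbind(x = x))
  expect_equal(unname(r2$p_value[["x"]]), o$p[[2]], tolerance = 1e-9)
})

test_that("slope, correlation and sd-ratio identities hold", {
  set.seed(77)
  for (k in 1:20) {
    x <- rnorm(60)
    y <- rnorm(60, 0.3 * x)
    r <- univariate_sensitivity(y, x, min_n = 30)
    expect_equal(unname(r$coefficients[["x"]]), r$r * sd(y) / sd(x),
      tolerance = 1e-10
    )
    # on standardized inputs the slope equals the correlation
    xs <- as.numeric(scale(x))
    ys <- as.numeric(scale(y))
    rs <- univariate_sensitivity(ys, xs, min_n = 30)
    expect_equal(unname(rs$coefficients[["x"]]), rs$r, tolerance = 1e-10)
  }
})

# partial sensitivity -----------------------------------------------------

test_that("orthogonal regressors reproduce univariate slopes with unit VIF", {
  set.seed(5)
  raw <- matrix(rnorm(300 * 2), 300, 2)
  Q <- qr.Q(qr(cbind(1, raw)))[, 2:3] # exactly orthogonal, zero-mean
  X <- Q %*% diag(c(3, 5))
  colnames(X) <- c("a", "b")
  y <- 0.5 * X[, 1] - 0.2 * X[, 2] + rnorm(300, 0, 0.3)
  fit <- partial_sensitivity(y, X, min_n = 30)
  ua <- univariate_sensitivity(y, X[, 1], min_n = 30)
  ub <- univariate_sensitivity(y, X[, 2], min_n = 30)
  expect_equal(unname(fit$coefficients[["a"]]),
    unname(ua$coefficients[["x"]]),
    tolerance = 1e-10
  )
  expect_equal(unname(fit$coefficients[["b"]]),
    unname(ub$coefficients[["x"]]),
    tolerance = 1e-10
  )
  expect_equal(unname(fit$vif), c(1, 1), tolerance = 1e-10)
})

test_that("two-regressor VIFs are identical and match the closed form", {
  set.seed(6)
  raw <- matrix(rnorm(500 * 2), 500, 2)
  Q <- qr.Q(qr(cbind(1, raw)))[, 2:3]
  u1 <- Q[, 1] / sd(Q[, 1])
  u2o <- Q[, 2] / sd(Q[, 2])
  rho <- 0.6
  X <- cbind(pa = u1, par = rho * u1 + sqrt(1 - rho^2) * u2o)
  y <- 0.6 * X[, 1] - 0.4 * X[, 2] + rnorm(500, 0, 0.3)
  fit <- partial_sensitivity(y, X, min_n = 30)
  expect_identical(fit$vif[["pa"]], fit$vif[["par"]])
  expect_equal(unname(fit$vif[["pa"]]), 1 / (1 - rho^2), tolerance = 1e-9)
  expect_equal(fit$beta_diff,
    unname(fit$coefficients[["pa"]] - fit$coefficients[["par"]]),
    tolerance = 1e-15
  )
  # against the independent auxiliary-regression oracle
  expect_equal(unname(fit$vif), unname(oracle_vif(X)), tolerance = 1e-9)
})

test_that("a single-regressor partial fit reduces to the univariate fit", {
  set.seed(7)
  x <- rnorm(100)
  y <- 0.3 * x + rnorm(100)
  f1 <- partial_sensitivity(y, cbind(x = x), min_n = 30)
  f2 <- univariate_sensitivity(y, x, min_n = 30)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
})

test_that("rank deficiency yields a missing result with infinite VIF", {
  set.seed(8)
  x <- rnorm(50)
  fit <- partial_sensitivity(rnorm(50), cbind(a = x, b = x), min_n = 30)
  expect_false(fit$ok)
  expect_equal(fit$reason, "rank_deficient")
  expect_true(all(is.infinite(fit$vif)))
})

# relative contributions --------------------------------------------------

test_that("relative contributions normalize to one and flag a zero sum", {
  expect_equal(relative_contributions(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(relative_contributions(c(2, -1)), c(2, -1))
  set.seed(9)
  for (k in 1:25) {
    b <- rnorm(sample(2:9, 1))
    if (sum(b) == 0) next
    expect_lt(abs(sum(relative_contributions(b)) - 1), 1e-12)
  }
  expect_error(relative_contributions(c(2, -2)), "sum to zero")
})

# lagged sensitivity ------------------------------------------------------

test_that("lag zero is bit-identical to the plain univariate estimate", {
  set.seed(10)
  y <- rnorm(120)
  x <- rnorm(120)
  expect_identical(
    lagged_sensitivity(y, x, 0L, min_n = 30),
    univariate_sensitivity(y, x, min_n = 30)
  )
})

test_that("a constructed one-step shift is recovered exactly", {
  set.seed(11)
  x <- rnorm(300)
  y <- c(NA, x[-300]) # y_t = x_{t-1} exactly
  r <- lagged_sensitivity(y, x, -1L, min_n = 30)
  expect_equal(unname(r$coefficients[["x"]]), 1, tolerance = 1e-10)
  expect_equal(r$r, 1, tolerance = 1e-12)
  r0 <- lagged_sensitivity(y, x, 0L, min_n = 30)
  expect_lt(abs(r0$coefficients[["x"]]), 0.2)
  expect_error(lagged_sensitivity(y, x, 300L), "smaller")
})

test_that("a lag-1 arid pixel shows |S(-1)| > |S(0)| in a tau sweep", {
  set.seed(12)
  s <- arid_pixel_series(n = 920, lag = 1)
  svals <- vapply(c(-2, -1, 0, 1, 2), function(tau) {
    unname(lagged_sensitivity(s$gpp, s$cf, tau, min_n = 30)$coefficients[2])
  }, 1)
  expect_gt(abs(svals[2]), abs(svals[3]))
  expect_gt(abs(svals[2]), abs(svals[1]))
})

# lag-response profile ----------------------------------------------------

test_that("the profile recovers a constructed three-period delay", {
  set.seed(13)
  x <- rnorm(920)
  y <- c(rep(NA, 3), x[1:917]) + rnorm(920, 0, 0.2)
  prof <- lag_response_profile(y, x, l = 8, alpha = 0.001, min_n = 30)
  expect_equal(prof$effective_response_period, -3L)
  expect_equal(prof$taus, -(0:8))
  expect_gt(prof$betas[4], 0.9)
})

test_that("the profile is undefined without a significant response", {
  set.seed(14)
  prof <- lag_response_profile(rnorm(500), rnorm(500), l = 8, alpha = 0.001)
  expect_true(is.na(prof$effective_response_period))
  # constant regressor: collinear lagged design -> missing profile
  prof2 <- lag_response_profile(rnorm(500), rep(1, 500), l = 8)
  expect_false(prof2$ok)
})

# sensitivity maps and RMSE comparison -------------------------------------

test_that("sensitivity maps respect masks and missing pixels", {
  w <- make_world(world_config(n_lat = 3, n_lon = 6, n_years = 6, seed = 15))
  gpp <- standardize_field(w$fields$gpp)
  cf <- standardize_field(w$fields$cf)
  gpp$values[, 1, 1] <- NA # an all-missing pixel
  m <- sensitivity_map(gpp, cf, min_n = 30)
  expect_true(is.na(m$S[1, 1]) && is.na(m$P[1, 1]) && is.na(m$N[1, 1]))
  mask <- matrix(TRUE, 3, 6)
  mask[2, ] <- FALSE
  m2 <- sensitivity_map(gpp, cf, mask = mask, min_n = 30)
  expect_true(all(is.na(m2$S[2, ])))
  expect_false(all(is.na(m2$S[3, ])))
})

test_that("nested RMSE comparison favours the richer model", {
  set.seed(16)
  x <- rnorm(400)
  z <- rnorm(400)
  y <- 0.5 * x - 0.3 * z + rnorm(400)
  cmp <- model_rmse_comparison(y, x, cbind(x = x, z = z))
  expect_gte(cmp$rmse_single, cmp$rmse_pair)
  # response driven by the single regressor alone: both models match it
  y2 <- 0.8 * x + rnorm(400, 0, 0.1)
  cmp2 <- model_rmse_comparison(y2, x, cbind(x = x, z = z))
  expect_lt(abs(cmp2$rmse_single - cmp2$rmse_pair), 0.01)
})

test_that("bivariate parameter recovery meets the replicate criterion", {
  # scaled-down version of the recovery property (full run in acceptance)
  set.seed(17)
  hits <- replicate(60, {
    pa <- rnorm(920)
    par <- rnorm(920)
    y <- 0.6 * pa - 0.4 * par + rnorm(920, 0, 0.3)
    fit <- partial_sensitivity(y, cbind(pa = pa, par = par), min_n = 30)
    all(abs(fit$coefficients[c("pa", "par")] - c(0.6, -0.4)) < 0.05)
  })
  expect_gte(mean(hits), 0.95)
})
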