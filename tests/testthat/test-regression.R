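test_that("an exact line is recovered with R^2 = 1 for any positive weights", {
  x <- c(0.1, 0.25, 0.4, 0.6, 0.85)
  y <- 2 * x + 1
  f <- suppressWarnings(weighted_linear_fit(x, y, ci95 = c(1, 0.2, 5, 0.7, 0.01)))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
})

test_that("equal weights reduce to ordinary least squares (closed-form oracle)", {
  set.seed(21)
  x <- runif(12)
  y <- 3e-7 + 4e-7 * x + rnorm(12, 0, 5e-8)
  f <- weighted_linear_fit(x, y, ci95 = rep(0.33, 12))
  orc <- ols_oracle(x, y)
  expect_equal(coef(f), orc, tolerance = 1e-12)
})

test_that("noiseless synthetic photoinactivation regressions recover their line", {
  # generating line on the scale of Phi_i PSII versus excitation pressure
  d <- make_regression_set(3.731e-7, 4.046e-7,
                           x_design = seq(0.1, 0.9, length.out = 7))
  f <- weighted_linear_fit(d$x, d$rate, d$rate_ci95)
  expect_equal(f$slope, 3.731e-7, tolerance = 1e-9)
  expect_equal(f$intercept, 4.046e-7, tolerance = 1e-9)
})

test_that("weighted fit is scale equivariant; R^2 and p-values unchanged", {
  set.seed(5)
  d <- make_regression_set(1.1e-4, 1e-5, x_design = seq(0.1, 0.9, 0.2),
                           noise = 2e-5, n_reps = 2)
  f1 <- weighted_linear_fit(d$x, d$rate, d$rate_ci95)
  k <- 1e6
  f2 <- weighted_linear_fit(d$x, d$rate * k, d$rate_ci95 * k)
  expect_equal(f2$slope, k * f1$slope)
  expect_equal(f2$intercept, k * f1$intercept)
  expect_equal(f2$r_squared, f1$r_squared)
  expect_equal(f2$slope_p, f1$slope_p)
  expect_equal(f2$intercept_p, f1$intercept_p)
})

test_that("degenerate designs are rejected", {
  expect_error(weighted_linear_fit(rep(1, 5), 1:5), "degenerate")
  expect_error(weighted_linear_fit(1:2, 1:2), "at least 3")
})

test_that("interaction test recovers a constructed slope difference exactly", {
  x <- rep(seq(0.1, 0.9, length.out = 6), 2)
  g <- rep(c("A", "B"), each = 6)
  y <- ifelse(g == "A", 1e-7 + 2e-7 * x[1:6], 1e-7 + 4e-7 * x[1:6])
  it <- suppressWarnings(interaction_test(x, y, group = g))
  expect_equal(unname(it$interaction_coef), 2e-7, tolerance = 1e-12)

  y_same <- 1e-7 + 2e-7 * x
  it0 <- suppressWarnings(interaction_test(x, y_same, group = g))
  expect_equal(unname(it0$interaction_coef), 0, tolerance = 1e-15)

  expect_error(interaction_test(x, y, group = rep("A", 12)), "2 levels")
})

test_that("interaction test holds its size under a true null", {
  set.seed(42)
  rejections <- 0
  for (r in 1:500) {
    d <- make_regression_set(3.7e-7, 4.0e-7,
                             x_design = seq(0.1, 0.9, length.out = 6),
                             noise = 5e-8, n_reps = 2)
    g <- rep(c("A", "B"), length.out = nrow(d))
    it <- interaction_test(d$x, d$rate, d$rate_ci95, g)
    if (it$p_interaction < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / 500, 0.07)
})

test_that("exponential growth rates come out of the log-linear fit", {
  expect_equal(suppressWarnings(fit_exponential_growth(0:6, 100 * 2^(0:6)))$mu,
               log(2), tolerance = 1e-12)
  expect_equal(suppressWarnings(fit_exponential_growth(0:5, rep(40, 6)))$mu, 0,
               tolerance = 1e-12)
  expect_equal(suppressWarnings(fit_exponential_growth(0:8, 100 * exp(0.3 * (0:8))))$mu,
               0.3, tolerance = 1e-12)
  expect_error(fit_exponential_growth(0:3, c(1, 2, -1, 3)), "positive")
  expect_error(fit_exponential_growth(c(0, 1, 1), c(1, 2, 3)), "increasing")
})
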