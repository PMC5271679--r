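test_that("presets encode the representative treatment ground truths", {
  blue <- scenario_preset("blue-1200")
  red <- scenario_preset("red-1200")
  expect_equal(blue$sigma_i, 1.23e-4)
  expect_equal(blue$sigma_i / blue$sigma_psii_2s, 7.2e-7)
  expect_equal(red$sigma_i, 1.65e-5)
  expect_equal(red$sigma_i / red$sigma_psii_2s, 2.8e-7)
  expect_error(scenario_preset("blue-1200", bogus = 1), "unknown preset fields")
})

test_that("noiseless time course follows the exponential dose decay", {
  fx <- fixture_tc("blue-1200")
  ds <- dose_series(fx$protocol, fx$preset$sigma_psii_2s)
  # independent closed-form evaluation at each period's cumulative dose
  expected <- fx$preset$amplitude * exp(-fx$preset$sigma_i * ds$cum_incident_A2)
  expect_equal(fx$tc$fv_fm_2s, expected, tolerance = 1e-9)
  # end-of-treatment attenuation: growth period at 260 plus 7 x 1200
  dose9 <- (260 + 7 * 1200) * 327 * 6.022e-3
  expect_equal(fx$tc$fv_fm_2s[9] / fx$tc$fv_fm_2s[1], exp(-1.23e-4 * dose9),
               tolerance = 1e-9)
})

test_that("generation is reproducible under its seed and varies across seeds", {
  p <- scenario_preset("blue-1200", noise_sd = 0.01)
  a <- make_timecourse(p, seed = 9)
  b <- make_timecourse(p, seed = 9)
  c <- make_timecourse(p, seed = 10)
  expect_identical(a$fv_fm_2s, b$fv_fm_2s)
  expect_false(identical(a$fv_fm_2s, c$fv_fm_2s))
})

test_that("optional flashlet traces refit to the period-level parameters", {
  p <- scenario_preset("blue-1200")
  tc <- make_timecourse(p, with_traces = TRUE)
  traces <- attr(tc, "traces")
  expect_length(traces, nrow(tc))
  fit <- fit_induction(traces[[5]]$after_2s_dark)
  expect_equal(fit$sigma_PSII, tc$sigma_psii_2s[5], tolerance = 1e-5)
  expect_equal(fit$F0, tc$F0_prime_2s[5], tolerance = 1e-5)
  expect_equal(fit$FM, tc$FM_prime_2s[5], tolerance = 1e-5)
})

test_that("regression sets with a minimal design still fit", {
  d <- make_regression_set(2, 1, x_design = c(0.1, 0.5, 0.9))
  expect_equal(nrow(d), 3)
  f <- weighted_linear_fit(d$x, d$rate, d$rate_ci95)
  expect_equal(coef(f), c(intercept = 1, slope = 2), tolerance = 1e-10)
})

test_that("mean fitted slope over many noisy sets is unbiased (MC oracle)", {
  set.seed(7)
  slopes <- replicate(300, {
    d <- make_regression_set(3.731e-7, 4.046e-7,
                             x_design = seq(0.05, 0.95, length.out = 8),
                             noise = 8e-8, n_reps = 2)
    coef(weighted_linear_fit(d$x, d$rate, d$rate_ci95))[["slope"]]
  })
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 3.731e-7), 2 * mc_se + 1e-12)
})

test_that("scenarios round-trip through CSV plus manifest", {
  dir <- withr::local_tempdir()
  p <- scenario_preset("red-1200", noise_sd = 0.005)
  paths <- write_scenario(p, dir)
  tc <- read_timecourse_csv(paths[["timecourse"]])
  expect_s3_class(tc, "treatment_timecourse")
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$ground_truth$sigma_i, 1.65e-5)
  expect_equal(man$ground_truth$phi_i_psii, 2.8e-7)
  # fits on the re-read course see the protocol rebuilt from metadata
  fit <- fit_sigma_i(tc, attr(tc, "protocol"))
  expect_equal(fit$rate, 1.65e-5, tolerance = 0.2)
})
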