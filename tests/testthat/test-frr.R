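test_that("flashlet train validates timing and dose", {
  tr <- flashlet_train()
  expect_equal(tr$n_flashlets, 40L)
  expect_equal(tr$total_duration_us, 40 * (1.2 + 2.0))
  expect_error(flashlet_train(n_flashlets = 2), "n_flashlets")
  expect_error(flashlet_train(flashlet_dose = 0))
})

test_that("simulated induction saturates at FM and stays at F0 without excitation", {
  # enormous cumulative dose: every centre closes within a few flashlets
  tr <- flashlet_train(flashlet_dose = 1)
  sim <- simulate_induction(0.2, 1.0, sigma_psii = 170, rho = 0, train = tr)
  expect_equal(sim$fluorescence[40], 1.0, tolerance = 1e-10)

  sim0 <- simulate_induction(0.2, 1.0, sigma_psii = 0)
  expect_equal(sim0$fluorescence, rep(0.2, 40), tolerance = 1e-12)
})

test_that("rho = 0 closure matches the Poisson closed form in the small-dose limit", {
  sigma <- 170
  # flashlet dose well under 0.001 / sigma
  tr <- flashlet_train(n_flashlets = 40, flashlet_dose = 1e-6)
  sim <- simulate_induction(F0 = 0.2, FM = 1.0, sigma_psii = sigma, rho = 0,
                            train = tr)
  # at rho = 0 the yield is linear in closure, so invert it exactly
  C_model <- (sim$fluorescence - 0.2) / 0.8
  C_oracle <- closure_poisson(sigma, sim$dose_before)
  expect_equal(C_model, C_oracle, tolerance = 1e-3)
})

test_that("noiseless traces rise monotonically", {
  for (rho in c(0, 0.25, 0.6)) {
    sim <- simulate_induction(0.3, 1.2, 150, rho = rho)
    expect_true(all(diff(sim$fluorescence) >= 0), info = paste("rho =", rho))
  }
})

test_that("simulation rejects non-physical parameters and is seed-reproducible", {
  expect_error(simulate_induction(1.0, 0.5, 170), "FM > F0")
  expect_error(simulate_induction(0.2, 1.0, 170, rho = 1), "rho")
  a <- simulate_induction(0.2, 1, 170, 0.3, noise_sd = 0.01, seed = 11)
  b <- simulate_induction(0.2, 1, 170, 0.3, noise_sd = 0.01, seed = 11)
  expect_identical(a$fluorescence, b$fluorescence)
})

test_that("noiseless round trip recovers all four parameters", {
  cases <- list(c(0.2, 1.0, 170, 0.3), c(0.15, 0.8, 250, 0), c(0.4, 1.6, 90, 0.55))
  for (p in cases) {
    sim <- simulate_induction(p[1], p[2], p[3], p[4])
    fit <- fit_induction(sim)
    expect_equal(unname(coef(fit)), p, tolerance = 1e-6)
    expect_equal(fit$fv_fm, (p[2] - p[1]) / p[2], tolerance = 1e-6)
  }
})

test_that("flat traces raise a no-variable-fluorescence error", {
  tr <- flashlet_train()
  expect_error(fit_induction(rep(0.2, 40), train = tr), "no variable fluorescence")
})

test_that("FV/FM is invariant under uniform scaling of the trace", {
  sim <- simulate_induction(0.2, 1.0, 170, 0.3, noise_sd = 0.003, seed = 3)
  f1 <- fit_induction(sim)
  scaled <- sim
  scaled$fluorescence <- sim$fluorescence * 7.5
  f2 <- fit_induction(scaled)
  expect_equal(f1$fv_fm, f2$fv_fm, tolerance = 1e-6)
  expect_equal(f1$sigma_PSII, f2$sigma_PSII, tolerance = 1e-6)
})

test_that("sigma_PSII 95% CI covers truth in at least 90 of 100 noisy fits", {
  hits <- 0
  for (s in 1:100) {
    sim <- simulate_induction(0.2, 1.0, 170, 0.3, noise_sd = 0.005, seed = s)
    fit <- tryCatch(fit_induction(sim), error = function(e) NULL)
    if (!is.null(fit) && abs(fit$sigma_PSII - 170) <= fit$ci95[["sigma_PSII"]])
      hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("induction traces survive a CSV round trip", {
  sim <- simulate_induction(0.2, 1, 170, 0.3, noise_sd = 0.002, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_induction_csv(sim, path, trace_id = "t1")
  back <- read_induction_csv(path, train = sim$train)
  expect_equal(back[["t1"]]$fluorescence, sim$fluorescence)
  expect_equal(back[["t1"]]$context, sim$context)
})
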