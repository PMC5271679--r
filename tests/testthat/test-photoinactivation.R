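test_that("sustained NPQ influence is the floored yield difference", {
  expect_equal(sustained_npq_influence(0.40, 0.35), 0.05)
  expect_equal(sustained_npq_influence(0.30, 0.35), 0)
  expect_equal(sustained_npq_influence(0.42, 0.42), 0)
  expect_error(sustained_npq_influence(1.2, 0.3))
})

test_that("NPQ correction restores the generating decay and is identity at zero influence", {
  fx <- fixture_tc("blue-1200")
  corr <- apply_npq_correction(fx$tc)
  expect_equal(attr(corr, "npq_influence"), 0)
  expect_equal(corr$fv_fm_2s, fx$tc$fv_fm_2s)

  fx2 <- fixture_tc("blue-1200", npq_influence = 0.05)
  corr2 <- apply_npq_correction(fx2$tc)
  lit <- fx2$tc$role %in% c("growth", "treatment")
  # recovery-period dose slightly exceeds the period-9 dose, so the
  # recovered influence is marginally below the generating value
  expect_equal(attr(corr2, "npq_influence"), 0.05, tolerance = 0.01)
  expect_equal(corr2$fv_fm_2s[lit] - fx2$tc$fv_fm_2s[lit],
               rep(attr(corr2, "npq_influence"), sum(lit)))

  norec <- fx$tc[fx$tc$role != "recovery", ]
  expect_error(apply_npq_correction(norec), "recovery")
})

test_that("correction flattens the apparent decay (smaller sigma_i)", {
  fx <- fixture_tc("blue-1200", npq_influence = 0.06)
  f_corr <- fit_sigma_i(fx$tc, fx$protocol, npq_correct = TRUE)
  f_raw <- fit_sigma_i(fx$tc, fx$protocol, npq_correct = FALSE)
  expect_lt(f_corr$rate, f_raw$rate)
  expect_equal(f_corr$rate, fx$preset$sigma_i, tolerance = 1e-3)
})

test_that("noiseless fits recover the generating sigma_i and Phi_i exactly", {
  for (nm in c("blue-1200", "red-1200")) {
    fx <- fixture_tc(nm)
    fs <- fit_sigma_i(fx$tc, fx$protocol)
    fp <- fit_phi_i(fx$tc, fx$protocol)
    expect_equal(fs$rate, fx$preset$sigma_i, tolerance = 1e-6)
    expect_equal(fp$rate, fx$preset$sigma_i / fx$preset$sigma_psii_2s,
                 tolerance = 1e-6)
    expect_equal(fs$amplitude, fx$preset$amplitude, tolerance = 1e-6)
    expect_gt(fs$r_squared, 0.999999)
    # fitted curve is monotone and the amplitude tops the observed series
    expect_true(all(diff(predict(fs)) <= 0))
    expect_gte(fs$amplitude, max(fs$y) - 1e-9)
  }
})

test_that("Phi_i x sigma_PSII'2s equals sigma_i under a constant cross section", {
  fx <- fixture_tc("red-1200")
  fs <- fit_sigma_i(fx$tc, fx$protocol)
  fp <- fit_phi_i(fx$tc, fx$protocol)
  expect_equal(fp$rate * fx$preset$sigma_psii_2s, fs$rate, tolerance = 1e-6)
})

test_that("point estimates are invariant to a uniform CI rescaling", {
  fx <- fixture_tc("blue-1200", noise_sd = 0.01)
  tc2 <- fx$tc
  tc2$fv_fm_2s_ci95 <- tc2$fv_fm_2s_ci95 * 13
  for (w in c("inverse_ci", "inverse_ci2")) {
    a <- fit_sigma_i(fx$tc, fx$protocol, weighting = w)
    b <- fit_sigma_i(tc2, fx$protocol, weighting = w)
    expect_equal(a$rate, b$rate, tolerance = 1e-9)
    expect_equal(a$amplitude, b$amplitude, tolerance = 1e-9)
  }
})

test_that("a constant series yields sigma_i = 0 and rising series warn", {
  fx <- fixture_tc("blue-1200", sigma_i = 0)
  fit <- fit_sigma_i(fx$tc, fx$protocol)
  expect_equal(fit$rate, 0, tolerance = 1e-12)

  rising <- fx$tc
  rising$fv_fm_2s <- seq(0.3, 0.48, length.out = nrow(rising))
  expect_warning(fit_sigma_i(rising, fx$protocol, npq_correct = FALSE),
                 "rises|pinned")
})

test_that("decay fit refuses short or degenerate input", {
  fx <- fixture_tc("blue-1200")
  short <- fx$tc[c(1:3, 10), ]
  expect_error(fit_sigma_i(short, fx$protocol), "at least 4")
})

test_that("sigma_i 95% CI covers truth in at least 90 of 100 noisy pipelines", {
  hits <- 0
  for (s in 1:100) {
    p <- scenario_preset("blue-1200", noise_sd = 0.01)
    tc <- make_timecourse(p, seed = s)
    fit <- fit_sigma_i(tc, attr(tc, "protocol"))
    if (abs(fit$rate - p$sigma_i) <= fit$ci95[["rate"]]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
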