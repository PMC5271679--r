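test_that("unit conversions respect the exact m^2 / A^2 identity", {
  expect_equal(quanta_A2_per_umol, 6.022e-3)
  expect_identical(quanta_A2_to_photons_m2(photons_m2_to_quanta_A2(3.7e22)),
                   3.7e22)
  expect_equal(incident_quanta_A2(1, 1), 6.022e-3)
})

test_that("default protocol is 10 x 327 s with dark, growth, treatment, recovery", {
  pr <- treatment_protocol(700, "blue_455nm", growth_light = 75)
  expect_equal(nrow(pr), 10)
  expect_equal(sum(pr$duration_s), 3270)
  expect_equal(pr$intensity, c(0, 75, rep(700, 7), 20))
  expect_equal(pr$role[c(1, 2, 10)], c("dark", "growth", "recovery"))
})

test_that("cumulative incident photons matches hand arithmetic", {
  # 8 dose-accruing periods x 327 s at a constant 1200 umol m^-2 s^-1
  pr <- treatment_protocol(1200, "blue_455nm", growth_light = 1200)
  got <- cumulative_incident_photons(pr, 9)
  expect_equal(got, 1200 * 6.022e17 * 8 * 327, tolerance = 1e-12)
  expect_equal(photons_m2_to_quanta_A2(got), 1.8904e4, tolerance = 1e-4)

  dark <- treatment_protocol(0, "blue_455nm", growth_light = 0,
                             recovery_intensity = 0)
  expect_equal(cumulative_incident_photons(dark, 10), 0)
})

test_that("dose accrual is additive across periods", {
  pr <- treatment_protocol(860, "red_655nm", growth_light = 30)
  for (n in 2:10) {
    expect_equal(cumulative_incident_photons(pr, n),
                 cumulative_incident_photons(pr, n - 1) +
                   incident_photons_m2(pr$intensity[n], pr$duration_s[n]))
  }
})

test_that("delivered photons per PSII scale linearly with the cross section", {
  pr <- treatment_protocol(1200, "blue_455nm", growth_light = 1200)
  ds <- dose_series(pr, sigma_psii_2s = 170.8)
  # sigma constant 170.8 A^2 on an incident dose of 1.8904e4 quanta A^-2
  expect_equal(ds$cum_delivered_psii[9], 170.8 * ds$cum_incident_A2[9])
  expect_equal(ds$cum_delivered_psii[9], 3.229e6, tolerance = 1e-3)

  expect_equal(delivered_photons_per_psii(ds, 0), rep(0, 10))
  half <- delivered_photons_per_psii(ds, 170.8 / 2)
  expect_equal(2 * half, ds$cum_delivered_psii)
  expect_error(dose_series(pr, sigma_psii_2s = -1), ">= 0")
})

test_that("cumulative dose series are non-decreasing", {
  pr <- treatment_protocol(450, "red_655nm", growth_light = 260)
  ds <- dose_series(pr, sigma_psii_2s = 60)
  expect_true(all(diff(ds$cum_incident_A2) >= 0))
  expect_true(all(diff(ds$cum_delivered_psii) >= 0))
})

test_that("custom period records build a valid protocol", {
  pr <- as_treatment_protocol(data.frame(
    duration_s = c(100, 200, 200, 200, 100),
    intensity = c(0, 50, 900, 900, 20),
    colour = c("dark", "growth", "blue_455nm", "blue_455nm",
               "lowlight_recovery")))
  expect_s3_class(pr, "treatment_protocol")
  expect_equal(pr$t_end_s[5], 800)
  expect_error(as_treatment_protocol(data.frame(
    duration_s = -1, intensity = 0, colour = "dark")), "durations")
})
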