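#' Ground-truth scenario presets for synthetic data
#'
#' A scenario preset bundles everything needed to generate a synthetic
#' photoinactivation experiment with known ground truth: the light-shift
#' protocol, the generating decay parameters, the noise model and a seed.
#' Two named presets reproduce the representative blue- and red-light
#' treatments of a high-light-grown *Prochlorococcus*-type culture
#' (growth 260, treatment 1200 umol photons m^-2 s^-1):
#' \describe{
#'   \item{`"blue-1200"`}{sigma_i = 1.23e-4 A^2 quanta^-1,
#'     Phi_i PSII = 7.2e-7, hence constant sigma_PSII'2s =
#'     sigma_i/Phi_i = 170.83 A^2 quanta^-1; noiseless.}
#'   \item{`"red-1200"`}{sigma_i = 1.65e-5, Phi_i PSII = 2.8e-7,
#'     sigma_PSII'2s = 58.93 A^2 quanta^-1; noiseless.}
#' }
#' Any field can be overridden through `...`.
#'
#' @param name `"blue-1200"`, `"red-1200"` or `"custom"`.
#' @param ... overrides for any preset field: `growth_light`,
#'   `treatment_intensity`, `treatment_colour`, `F0`, `amplitude`
#'   (FV'2s/FM'2s at zero dose), `sigma_i`, `sigma_psii_2s`,
#'   `sigma_drift` (fractional per-period change in sigma_PSII'2s),
#'   `npq_influence`, `one_minus_qp`, `rho`, `noise_sd` (Gaussian sd on
#'   yield ratios), `sigma_rel_sd` (relative sd on cross sections),
#'   `trace_noise_sd` (flashlet-level noise), `ci_floor`, `seed`,
#'   `species`.
#' @return An object of class `"scenario_preset"` (a list).
#' @examples
#' scenario_preset("blue-1200")$sigma_psii_2s
#' @export
scenario_preset <- function(name = c("blue-1200", "red-1200", "custom"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    species = "Prochlorococcus-like",
    growth_light = 260,
    treatment_intensity = 1200,
    treatment_colour = "blue_455nm",
    F0 = 0.2,
    amplitude = 0.45,
    sigma_i = 1.23e-4,
    sigma_psii_2s = 1.23e-4 / 7.2e-7,
    sigma_drift = 0,
    npq_influence = 0,
    one_minus_qp = 0.65,
    rho = 0.3,
    noise_sd = 0,
    sigma_rel_sd = 0,
    trace_noise_sd = 0,
    ci_floor = 1e-3,
    seed = 1234
  )
  if (name == "red-1200") {
    base$treatment_colour <- "red_655nm"
    base$sigma_i <- 1.65e-5
    base$sigma_psii_2s <- 1.65e-5 / 2.8e-7
    base$one_minus_qp <- 0.35
  }
  if (name == "custom") base$noise_sd <- 0.01
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown preset fields: ", paste(unknown, collapse = ", "))
  out <- modifyList(base, over)
  stopifnot(out$F0 > 0, out$amplitude > 0, out$amplitude < 1,
            out$sigma_i >= 0, out$sigma_psii_2s > 0,
            out$npq_influence >= 0, out$noise_sd >= 0,
            out$one_minus_qp >= 0, out$one_minus_qp <= 1,
            out$rho >= 0, out$rho < 1)
  structure(out, class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf("Scenario preset '%s' (%s)\n", x$name, x$species))
  cat(sprintf("  growth %g, treatment %g umol m^-2 s^-1 (%s)\n",
              x$growth_light, x$treatment_intensity, x$treatment_colour))
  cat(sprintf("  sigma_i %.4g A^2 quanta^-1, sigma_PSII'2s %.4g A^2, Phi_i %.4g\n",
              x$sigma_i, x$sigma_psii_2s, x$sigma_i / x$sigma_psii_2s))
  cat(sprintf("  amplitude %.3g, NPQ influence %.3g, noise sd %.3g, seed %d\n",
              x$amplitude, x$npq_influence, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a synthetic treatment time course
#'
#' Forward model of a photoinactivation experiment under the light-shift
#' protocol. The photochemical yield FV'2s/FM'2s decays as
#' amplitude x exp(-sigma_i x cumulative incident dose); sustained NPQ
#' depresses the illuminated-period values by `npq_influence` and relaxes
#' in the terminal recovery period; Gaussian noise (sd `noise_sd`, with
#' point-to-point spread so that CI weighting matters) is added to the
#' yields and propagated into per-point 95% CI half-widths floored at
#' `ci_floor`. Fluorescence levels (FS, FM', F0'2s, FM'2s) are generated
#' consistently with the yields and with the preset's excitation pressure.
#'
#' @param preset a [scenario_preset()].
#' @param seed integer seed (defaults to the preset's).
#' @param with_traces also simulate the flashlet-level induction trace
#'   pair (under actinic / after 2 s dark) for each period, attached as
#'   attribute `"traces"`.
#' @return A `"treatment_timecourse"` data.frame (one row per period) with
#'   attributes `protocol` (the [treatment_protocol()]), `ground_truth`
#'   (the preset) and, if requested, `traces`.
#' @examples
#' tc <- make_timecourse(scenario_preset("blue-1200"))
#' tc$fv_fm_2s
#' @export
make_timecourse <- function(preset, seed = preset$seed, with_traces = FALSE) {
  stopifnot(inherits(preset, "scenario_preset"))
  set.seed(seed)
  protocol <- treatment_protocol(preset$treatment_intensity,
                                 preset$treatment_colour,
                                 growth_light = preset$growth_light)
  n <- nrow(protocol)
  sigma <- preset$sigma_psii_2s * (1 + preset$sigma_drift)^(protocol$period - 1)
  if (preset$sigma_rel_sd > 0)
    sigma <- sigma * (1 + rnorm(n, 0, preset$sigma_rel_sd))
  ds <- dose_series(protocol, sigma_psii_2s = sigma)

  y_true <- preset$amplitude * exp(-preset$sigma_i * ds$cum_incident_A2)
  y_meas <- y_true
  lit <- protocol$role %in% c("growth", "treatment")
  y_meas[lit] <- y_meas[lit] - preset$npq_influence

  if (preset$noise_sd > 0) {
    sd_i <- preset$noise_sd * runif(n, 0.6, 1.6)
    y_meas <- y_meas + rnorm(n, 0, sd_i)
    ci <- pmax(1.96 * sd_i, preset$ci_floor)
  } else {
    ci <- rep(preset$ci_floor, n)
  }
  y_meas <- pmin(pmax(y_meas, 1e-6), 1 - 1e-6)

  FM <- preset$F0 / (1 - preset$amplitude)
  FM_prime_2s <- FM * (0.5 + 0.5 * pmin(y_true / preset$amplitude, 1))
  F0_prime_2s <- FM_prime_2s * (1 - y_meas)
  f0p <- f0_prime(preset$F0, FM, FM_prime_2s)
  FM_prime <- ifelse(protocol$role == "dark", FM, 0.85 * FM_prime_2s)
  FS <- ifelse(protocol$role == "dark", preset$F0,
               FM_prime - (1 - preset$one_minus_qp) * (FM_prime - f0p))

  tc <- data.frame(
    period = protocol$period,
    elapsed_s = protocol$t_end_s,
    context = protocol$role,
    role = protocol$role,
    F0 = preset$F0, FM = FM,
    FS = FS, FM_prime = FM_prime,
    sigma_psii_prime = 0.9 * sigma,
    F0_prime_2s = F0_prime_2s,
    FM_prime_2s = FM_prime_2s,
    sigma_psii_2s = sigma,
    fv_fm_2s = y_meas,
    fv_fm_2s_ci95 = ci,
    species = preset$species,
    growth_light = preset$growth_light,
    treat_colour = preset$treatment_colour,
    treat_intensity = preset$treatment_intensity,
    stringsAsFactors = FALSE
  )
  out <- structure(tc, class = c("treatment_timecourse", "data.frame"),
                   protocol = protocol, ground_truth = preset)
  if (with_traces) {
    traces <- lapply(seq_len(n), function(i) {
      list(
        under_actinic = simulate_induction(
          F0 = FS[i], FM = FM_prime[i],
          sigma_psii = 0.9 * sigma[i], rho = preset$rho,
          noise_sd = preset$trace_noise_sd, context = "under_actinic"),
        after_2s_dark = simulate_induction(
          F0 = F0_prime_2s[i], FM = FM_prime_2s[i],
          sigma_psii = sigma[i], rho = preset$rho,
          noise_sd = preset$trace_noise_sd, context = "after_2s_dark"))
    })
    attr(out, "traces") <- traces
  }
  out
}

#' Generate a synthetic regression dataset
#'
#' Emulates a cross-treatment point cloud of rate estimates (sigma_i or
#' Phi_i PSII) versus a predictor (1 - qP or treatment intensity):
#' `rate = intercept + slope * x` plus heteroscedastic Gaussian noise,
#' with per-point 95% CI half-widths drawn with enough spread that CI
#' weighting matters. Ground truth is recorded in attributes.
#'
#' @param slope,intercept generating line.
#' @param x_design predictor values (replicated `n_reps` times).
#' @param noise typical noise sd on the rates (0 gives exact data with
#'   equal CIs).
#' @param n_reps replicates per design point.
#' @param seed integer seed.
#' @param ci_floor minimum CI half-width; defaults to 1e-3 of the typical
#'   response magnitude.
#' @return data.frame with columns `x`, `rate`, `rate_ci95`, `rep`;
#'   attributes `slope`, `intercept`.
#' @examples
#' d <- make_regression_set(2, 1, x_design = 1:5)
#' coef(weighted_linear_fit(d$x, d$rate, d$rate_ci95))
#' @export
make_regression_set <- function(slope, intercept, x_design, noise = 0,
                                n_reps = 1, seed = NULL, ci_floor = NULL) {
  if (diff(range(x_design)) <= 0) stop("x_design is degenerate")
  if (!is.null(seed)) set.seed(seed)
  x <- rep(x_design, times = n_reps)
  mu <- intercept + slope * x
  if (is.null(ci_floor))
    ci_floor <- 1e-3 * max(mean(abs(mu)), .Machine$double.eps)
  if (noise > 0) {
    sd_i <- noise * runif(length(x), 0.5, 2)
    rate <- mu + rnorm(length(x), 0, sd_i)
    ci <- pmax(1.96 * sd_i, ci_floor)
  } else {
    rate <- mu
    ci <- rep(ci_floor, length(x))
  }
  structure(data.frame(x = x, rate = rate, rate_ci95 = ci,
                       rep = rep(seq_len(n_reps), each = length(x_design))),
            slope = slope, intercept = intercept)
}

#' Representative budget scenario for a Synechococcus-type cell
#'
#' Builds a [psii_budget()] over a range of treatment intensities using
#' representative parameter values for a nutrient-replete, marine
#' *Synechococcus*-type picocyanobacterium under blue light: a large
#' effective antenna (sigma_PSII'2s = 250 A^2 quanta^-1), a
#' photoinactivation target size rising linearly with intensity
#' (sigma_i = 3.7e-5 + 1.0e-7 x I), and PSII openness declining with
#' light as qP = 1 / (1 + I/500).
#'
#' @param intensity treatment intensities, umol photons m^-2 s^-1.
#' @param costs a [cost_model()].
#' @return A `"psii_budget"`.
#' @export
synechococcus_budget_scenario <- function(intensity = seq(150, 1500, by = 150),
                                          costs = cost_model()) {
  sigma_i <- 3.7e-5 + 1.0e-7 * intensity
  qp <- 1 / (1 + intensity / 500)
  psii_budget(sigma_psii_2s = 250, sigma_i = sigma_i, qp = qp,
              intensity = intensity, costs = costs)
}
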