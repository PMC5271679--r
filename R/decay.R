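# Core weighted single-phase exponential decay fit:
#   y = amplitude * exp(-rate * x),
# y the (NPQ-corrected) FV'2s/FM'2s series, x the cumulative photon dose.
# Points are weighted by the inverse of their 95% CI half-width (the
# convention of the source analyses), optionally by 1/CI^2; rate is
# bounded >= 0; initialisation from a log-linear regression.
fit_decay_core <- function(x, y, ci95, weighting, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(ci95)) ok <- ok & is.finite(ci95) & ci95 > 0
  x <- x[ok]; y <- y[ok]
  ci95 <- if (is.null(ci95)) rep(1, length(y)) else ci95[ok]
  n <- length(y)
  if (n < 4) stop("need at least 4 finite points with positive CIs for the decay fit")
  if (any(y <= 0)) stop("FV'2s/FM'2s values must be positive")

  w <- switch(weighting,
              inverse_ci = 1 / ci95,
              inverse_ci2 = 1 / ci95^2,
              none = rep(1, n),
              stop("unknown weighting: ", weighting))

  # log-linear initialisation (OLS on the log scale)
  ll <- lm(log(y) ~ x)
  rate0 <- max(-coef(ll)[[2]], 0)
  # a decay indistinguishable from zero over the whole design starts at 0
  # exactly (tiny denormal starts make the initial model matrix singular)
  if (rate0 * max(abs(x)) < 1e-9) rate0 <- 0
  amp0 <- min(max(exp(coef(ll)[[1]]), 1e-6), 1 - 1e-9)
  rising <- coef(ll)[[2]] * max(abs(x)) > 1e-9

  df <- data.frame(x = x, y = y, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ amp * exp(-rate * x), data = df,
                      start = list(amp = amp0, rate = rate0),
                      weights = w,
                      lower = c(amp = 1e-9, rate = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) {
      if (rate0 > 0)
        stop("decay fit did not converge: ", conditionMessage(e))
      NULL  # no detectable decay: exact rate-0 solution below
    })
  if (is.null(fit)) {
    # flat (or rising, rate pinned at 0) series: amplitude is the weighted
    # mean, the rate and its curvature are exactly zero
    fit <- lm(y ~ 1, weights = w)
    est <- c(amp = unname(coef(fit)[1]), rate = 0)
    V <- matrix(0, 2, 2)
    V[1, 1] <- vcov(fit)[1, 1]
  } else {
    est <- coef(fit)
    V <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  }
  if (rising && est[["rate"]] <= .Machine$double.eps)
    warning("series rises with dose; rate pinned at 0")
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 2)
  se <- sqrt(pmax(diag(V), 0))
  yhat <- est[["amp"]] * exp(-est[["rate"]] * x)
  ybar_w <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - yhat)^2) / sum(w * (y - ybar_w)^2)
  list(amplitude = est[["amp"]], rate = est[["rate"]],
       ci95 = c(rate = unname(se[2]) * tq, amplitude = unname(se[1]) * tq),
       r_squared = r2, n = n, x = x, y = y, ci95_points = ci95,
       weights = w, fitted = yhat, fit = fit, conf_level = conf_level)
}

# Shared plumbing for the two public decay fits: resolve the dose
# abscissa, optionally NPQ-correct, drop the recovery period, fit.
fit_decay_tc <- function(tc, protocol, basis, weighting, npq_correct,
                         conf_level) {
  stopifnot(is.data.frame(tc), all(c("period", "fv_fm_2s") %in% names(tc)))
  if (inherits(protocol, "dose_series")) {
    ds <- protocol
  } else {
    stopifnot(inherits(protocol, "treatment_protocol"))
    sig <- if ("sigma_psii_2s" %in% names(tc)) {
      tc$sigma_psii_2s[match(protocol$period, tc$period)]
    } else NA_real_
    if (basis == "delivered" && any(!is.finite(sig[protocol$period >= 2 &
                                                   protocol$role != "recovery"])))
      stop("delivered-photon basis requires per-period sigma_psii_2s values")
    ds <- dose_series(protocol, sigma_psii_2s = sig)
  }
  infl <- 0
  sd_infl <- 0
  if (npq_correct) {
    # uncertainty of the influence estimate (difference of two measured
    # yields); propagated into the parameter CIs below because the
    # correction shifts all corrected points by a common error that
    # residuals cannot detect
    if (!is.null(tc$role) && "fv_fm_2s_ci95" %in% names(tc)) {
      rec_i <- which(tc$role == "recovery")[1]
      trt_i <- max(which(tc$role == "treatment"))
      if (is.finite(rec_i) && length(trt_i))
        sd_infl <- sqrt(tc$fv_fm_2s_ci95[rec_i]^2 +
                        tc$fv_fm_2s_ci95[trt_i]^2) / 1.96
    }
    tc <- apply_npq_correction(tc)
    infl <- attr(tc, "npq_influence")
  }
  keep <- if (!is.null(tc$role)) tc$role != "recovery" else
    tc$period < max(tc$period)
  tc_fit <- tc[keep, ]
  xcol <- if (basis == "incident") "cum_incident_A2" else "cum_delivered_psii"
  xx <- ds[[xcol]][match(tc_fit$period, ds$period)]
  if (any(!is.finite(xx)))
    stop("could not match time-course periods to the dose series")
  ci <- tc_fit$fv_fm_2s_ci95
  core <- fit_decay_core(xx, tc_fit$fv_fm_2s, ci, weighting, conf_level)
  if (npq_correct && sd_infl > 0) {
    # delta-method sensitivity of (amplitude, rate) to a common shift of
    # the corrected (illuminated) points: dtheta/dshift = (J'WJ)^-1 J'W 1_S
    lit <- tc_fit$role %in% c("growth", "treatment")
    lit <- lit[is.finite(xx) & is.finite(tc_fit$fv_fm_2s)]
    a <- core$amplitude; r <- core$rate
    J <- cbind(exp(-r * core$x), -a * core$x * exp(-r * core$x))
    W <- diag(core$weights, nrow = length(core$weights))
    sens <- tryCatch(solve(t(J) %*% W %*% J, t(J) %*% W %*% as.numeric(lit)),
                     error = function(e) c(0, 0))
    tq <- qt(1 - (1 - conf_level) / 2, df = core$n - 2)
    extra <- abs(c(amp = sens[1], rate = sens[2])) * sd_infl
    core$ci95["rate"] <- sqrt(core$ci95[["rate"]]^2 + (tq * extra[["rate"]])^2)
    core$ci95["amplitude"] <- sqrt(core$ci95[["amplitude"]]^2 +
                                   (tq * extra[["amp"]])^2)
  }
  core$basis <- basis
  core$npq_influence_applied <- infl
  core$weighting <- weighting
  core$dose_series <- ds
  structure(core, class = "decay_fit")
}

#' Fit the photoinactivation target size sigma_i
#'
#' Fits the single-phase exponential decay of the NPQ-corrected
#' FV'2s/FM'2s series against cumulative incident photons (quanta A^-2):
#' \deqn{FV'2s/FM'2s = (FV'2s/FM'2s)_{t=0} \, e^{-\sigma_i \times
#'   \mathrm{cumulative\ incident\ photons}}}
#' sigma_i (A^2 quanta^-1) is a target-size parameterisation of the
#' probability of PSII photoinactivation per photon incident on the cell.
#' Each point is weighted by the inverse of its 95% CI half-width to
#' account for the varying precision of individual yield estimates.
#'
#' @param tc treatment time course (data.frame with `period`, `fv_fm_2s`,
#'   `fv_fm_2s_ci95`, `role`, and `sigma_psii_2s` for the delivered basis).
#' @param protocol the [treatment_protocol()] the series was measured
#'   under, or a precomputed [dose_series()].
#' @param weighting `"inverse_ci"` (default, weight = 1/CI),
#'   `"inverse_ci2"` (classical inverse-variance) or `"none"`.
#' @param npq_correct apply [apply_npq_correction()] first (default TRUE;
#'   requires the recovery period).
#' @param conf_level confidence level for parameter intervals.
#' @return An object of class `"decay_fit"`: `rate` (sigma_i), `amplitude`
#'   (yield at zero dose), `ci95`, `r_squared`, `basis`,
#'   `npq_influence_applied`, `n`, and the fitted series.
#' @examples
#' tc <- make_timecourse(scenario_preset("blue-1200"))
#' fit <- fit_sigma_i(tc, attr(tc, "protocol"))
#' coef(fit)
#' @export
fit_sigma_i <- function(tc, protocol, weighting = c("inverse_ci",
                                                    "inverse_ci2", "none"),
                        npq_correct = TRUE, conf_level = 0.95) {
  weighting <- match.arg(weighting)
  fit_decay_tc(tc, protocol, "incident", weighting, npq_correct, conf_level)
}

#' Fit the photoinactivation yield Phi_i PSII
#'
#' As [fit_sigma_i()], but the abscissa is the cumulative number of photons
#' delivered to PSII photochemistry per complex (cumulative incident dose
#' in quanta A^-2 times the period-specific sigma_PSII'2s in A^2
#' quanta^-1). The fitted rate Phi_i PSII is a dimensionless yield — PSII
#' inactivated per photon delivered to PSII — which removes spectral and
#' antenna-regulation differences in excitation delivery. With a constant
#' sigma_PSII'2s, Phi_i PSII = sigma_i / sigma_PSII'2s.
#'
#' @inheritParams fit_sigma_i
#' @return A `"decay_fit"` with `basis = "delivered"`; `rate` is Phi_i PSII.
#' @examples
#' tc <- make_timecourse(scenario_preset("red-1200"))
#' fit <- fit_phi_i(tc, attr(tc, "protocol"))
#' coef(fit)
#' @export
fit_phi_i <- function(tc, protocol, weighting = c("inverse_ci",
                                                  "inverse_ci2", "none"),
                      npq_correct = TRUE, conf_level = 0.95) {
  weighting <- match.arg(weighting)
  fit_decay_tc(tc, protocol, "delivered", weighting, npq_correct, conf_level)
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  lab <- if (x$basis == "incident") "sigma_i (A^2 quanta^-1)"
         else "Phi_i PSII (PSII photon^-1)"
  cat(sprintf("Single-phase photoinactivation decay fit (%s basis)\n", x$basis))
  cat(sprintf("  %-28s %s +/- %s\n", lab, format(x$rate, digits = digits),
              format(x$ci95[["rate"]], digits = 3)))
  cat(sprintf("  %-28s %s +/- %s\n", "amplitude (yield at dose 0)",
              format(x$amplitude, digits = digits),
              format(x$ci95[["amplitude"]], digits = 3)))
  cat(sprintf("  R^2 = %.4f, n = %d, NPQ influence applied = %.4g\n",
              x$r_squared, x$n, x$npq_influence_applied))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  rn <- if (object$basis == "incident") "sigma_i" else "phi_i_psii"
  setNames(c(object$rate, object$amplitude), c(rn, "amplitude"))
}

#' @export
summary.decay_fit <- function(object, ...) {
  print(object)
  invisible(data.frame(
    parameter = names(coef(object)),
    estimate = unname(coef(object)),
    ci95_halfwidth = unname(object$ci95[c("rate", "amplitude")]),
    row.names = NULL))
}

#' @export
predict.decay_fit <- function(object, newdose = object$x, ...) {
  object$amplitude * exp(-object$rate * newdose)
}

#' @export
residuals.decay_fit <- function(object, ...) object$y - object$fitted

#' @export
plot.decay_fit <- function(x, ...) {
  xlab <- if (x$basis == "incident")
    "cumulative incident photons (quanta A^-2)"
  else "cumulative delivered photons (PSII^-1)"
  plot(x$x, x$y, xlab = xlab, ylab = "FV'2s/FM'2s",
       ylim = range(0, x$y + x$ci95_points, x$y - x$ci95_points), ...)
  arrows(x$x, x$y - x$ci95_points, x$x, x$y + x$ci95_points,
         angle = 90, code = 3, length = 0.02)
  xs <- seq(min(x$x), max(x$x), length.out = 200)
  lines(xs, predict(x, xs), col = if (x$basis == "incident") "blue3" else "red3")
  invisible(x)
}

#' Write decay-fit results to CSV
#'
#' One row per fit: rate, CI, amplitude, R^2, basis, NPQ influence.
#'
#' @param fits a `decay_fit` or list of them.
#' @param path file path.
#' @param labels optional row labels (treatment identifiers).
#' @export
write_decay_csv <- function(fits, path, labels = NULL) {
  if (inherits(fits, "decay_fit")) fits <- list(fits)
  df <- do.call(rbind, lapply(fits, function(f) data.frame(
    basis = f$basis, rate = f$rate, rate_ci95 = f$ci95[["rate"]],
    amplitude = f$amplitude, amplitude_ci95 = f$ci95[["amplitude"]],
    r_squared = f$r_squared, n = f$n,
    npq_influence = f$npq_influence_applied,
    weighting = f$weighting)))
  if (!is.null(labels)) df <- cbind(treatment = labels, df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
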