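#' Define a light-shift treatment protocol
#'
#' The standard photoinactivation treatment is 10 sequential periods of
#' 327 s (3270 s total): period 1 dark, period 2 at the culture's growth
#' irradiance, periods 3-9 at the treatment irradiance and colour, and
#' period 10 a low-light recovery phase (20 umol photons m^-2 s^-1) that
#' lets sustained NPQ relax while protein synthesis stays blocked.
#' A photophysiology measurement is taken at the end of each period.
#'
#' @param treatment_intensity treatment irradiance, umol photons m^-2 s^-1.
#' @param treatment_colour `"blue_455nm"` or `"red_655nm"`.
#' @param growth_light growth irradiance for period 2.
#' @param n_treatment number of treatment periods (default 7, periods 3-9).
#' @param period_s duration of each period, seconds.
#' @param recovery_intensity irradiance of the terminal recovery period.
#' @return An object of class `"treatment_protocol"`: a data.frame with
#'   columns `period`, `duration_s`, `intensity`, `colour`, `role` and
#'   `t_end_s`.
#' @examples
#' pr <- treatment_protocol(1200, "blue_455nm", growth_light = 260)
#' sum(pr$duration_s)  # 3270
#' @export
treatment_protocol <- function(treatment_intensity,
                               treatment_colour = c("blue_455nm", "red_655nm"),
                               growth_light = 75, n_treatment = 7,
                               period_s = 327, recovery_intensity = 20) {
  treatment_colour <- match.arg(treatment_colour)
  stopifnot(treatment_intensity >= 0, growth_light >= 0, n_treatment >= 1,
            period_s > 0, recovery_intensity >= 0)
  n <- n_treatment + 3
  df <- data.frame(
    period = seq_len(n),
    duration_s = period_s,
    intensity = c(0, growth_light, rep(treatment_intensity, n_treatment),
                  recovery_intensity),
    colour = c("dark", "growth", rep(treatment_colour, n_treatment),
               "lowlight_recovery"),
    role = c("dark", "growth", rep("treatment", n_treatment), "recovery"),
    stringsAsFactors = FALSE
  )
  df$t_end_s <- cumsum(df$duration_s)
  structure(df, class = c("treatment_protocol", "data.frame"))
}

#' Build a protocol from explicit period records
#'
#' @param periods data.frame with columns `duration_s`, `intensity`,
#'   `colour` (one row per period, in order).
#' @return A `"treatment_protocol"`.
#' @export
as_treatment_protocol <- function(periods) {
  stopifnot(is.data.frame(periods),
            all(c("duration_s", "intensity", "colour") %in% names(periods)))
  if (any(periods$duration_s <= 0)) stop("durations must be > 0")
  if (any(periods$intensity < 0)) stop("intensities must be >= 0")
  periods$period <- seq_len(nrow(periods))
  if (is.null(periods$role)) {
    periods$role <- "treatment"
    periods$role[1] <- "dark"
    if (nrow(periods) >= 2) periods$role[2] <- "growth"
    periods$role[nrow(periods)] <- "recovery"
  }
  periods$t_end_s <- cumsum(periods$duration_s)
  structure(periods[, c("period", "duration_s", "intensity", "colour",
                        "role", "t_end_s")],
            class = c("treatment_protocol", "data.frame"))
}

#' @export
print.treatment_protocol <- function(x, ...) {
  cat(sprintf("Light-shift protocol: %d periods, %.0f s total\n",
              nrow(x), sum(x$duration_s)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Cumulative incident photons through a protocol period
#'
#' Sums irradiance x duration over periods 2 through `through_period`,
#' converted at 6.022e17 photons per umol. The initial dark period is
#' excluded from dose accrual by convention (it delivers no photons in the
#' standard protocol anyway).
#'
#' @param protocol a [treatment_protocol()].
#' @param through_period 1-based period index (inclusive).
#' @return Cumulative incident photons m^-2 (scalar).
#' @examples
#' pr <- treatment_protocol(1200, "blue_455nm", growth_light = 1200)
#' cumulative_incident_photons(pr, 9)
#' @export
cumulative_incident_photons <- function(protocol, through_period) {
  stopifnot(inherits(protocol, "treatment_protocol"))
  if (through_period < 1 || through_period > nrow(protocol))
    stop("through_period out of range")
  if (protocol$intensity[1] > 0)
    warning("period 1 has non-zero intensity but is excluded from dose accrual")
  if (through_period < 2) return(0)
  idx <- 2:through_period
  sum(incident_photons_m2(protocol$intensity[idx], protocol$duration_s[idx]))
}

#' Per-period photon dose bookkeeping
#'
#' Tabulates, per protocol period, the incident photon dose (photons m^-2
#' and quanta A^-2), its running cumulative sum, and — when per-period
#' effective absorption cross sections are supplied — the photons delivered
#' to PSII photochemistry (incident dose in quanta A^-2 times that period's
#' sigma_PSII'2s in A^2 quanta^-1) and their cumulative sum. Period 1
#' (dark) accrues no dose.
#'
#' @param protocol a [treatment_protocol()].
#' @param sigma_psii_2s effective absorption cross section for PSII after
#'   2 s darkness, A^2 quanta^-1: scalar (recycled) or one value per period.
#' @return An object of class `"dose_series"` (a data.frame).
#' @examples
#' pr <- treatment_protocol(1200, "blue_455nm", growth_light = 260)
#' ds <- dose_series(pr, sigma_psii_2s = 170.8)
#' ds$cum_delivered_psii[9]
#' @export
dose_series <- function(protocol, sigma_psii_2s = NA_real_) {
  stopifnot(inherits(protocol, "treatment_protocol"))
  n <- nrow(protocol)
  sigma <- rep_len(sigma_psii_2s, n)
  if (any(!is.na(sigma) & sigma < 0)) stop("sigma_psii_2s must be >= 0")
  inc_m2 <- incident_photons_m2(protocol$intensity, protocol$duration_s)
  inc_m2[1] <- 0  # initial dark period excluded from accrual
  inc_A2 <- photons_m2_to_quanta_A2(inc_m2)
  delivered <- inc_A2 * sigma
  out <- data.frame(
    period = protocol$period,
    t_end_s = protocol$t_end_s,
    intensity = protocol$intensity,
    colour = protocol$colour,
    incident_photons_m2 = inc_m2,
    incident_quanta_A2 = inc_A2,
    cum_incident_m2 = cumsum(inc_m2),
    cum_incident_A2 = cumsum(inc_A2),
    sigma_psii_2s = sigma,
    delivered_psii = delivered,
    cum_delivered_psii = cumsum(delivered),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("dose_series", "data.frame"))
}

#' Cumulative photons delivered to PSII per complex
#'
#' @param dose a [dose_series()] (incident part is used).
#' @param sigma_psii_2s per-period sigma_PSII'2s, A^2 quanta^-1.
#' @return Cumulative delivered photons PSII^-1, one value per period.
#' @export
delivered_photons_per_psii <- function(dose, sigma_psii_2s) {
  stopifnot(inherits(dose, "dose_series"))
  sigma <- rep_len(sigma_psii_2s, nrow(dose))
  if (any(sigma < 0, na.rm = TRUE)) stop("sigma_psii_2s must be >= 0")
  cumsum(dose$incident_quanta_A2 * sigma)
}

#' @export
#' @param x a `dose_series`.
#' @param path file path.
#' @rdname dose_series
write_dose_csv <- function(x, path) {
  stopifnot(inherits(x, "dose_series"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
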