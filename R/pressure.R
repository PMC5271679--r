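#' Estimate F0' for cells under excitation
#'
#' Minimal fluorescence with PSII open cannot be measured directly under
#' actinic light, so it is estimated from the dark-adapted F0 and FM and
#' the light-acclimated FM'2s:
#' \deqn{F_0' = F_0 / \{(F_M - F_0)/F_M + F_0/F_M'2s\}}
#' Using FM'2s (measured 2 s after the actinic light ends) excludes the
#' cumulative influence of photoinactivation. When FM'2s = FM (no
#' quenching) the formula returns F0; quenching (FM'2s < FM) pulls F0'
#' below F0.
#'
#' @param F0 dark-adapted minimal fluorescence (> 0).
#' @param FM dark-adapted maximal fluorescence (> F0).
#' @param FM_prime_2s maximal fluorescence 2 s after excitation (> 0).
#' @return F0' (same relative units), vectorised.
#' @examples
#' f0_prime(0.2, 1.0, 1.0)  # 0.2
#' f0_prime(0.2, 1.0, 0.8)  # 0.19048
#' @export
f0_prime <- function(F0, FM, FM_prime_2s) {
  if (any(!(FM > F0 & F0 > 0))) stop("require FM > F0 > 0")
  if (any(FM_prime_2s <= 0)) stop("require FM_prime_2s > 0")
  F0 / ((FM - F0) / FM + F0 / FM_prime_2s)
}

#' Excitation pressure on PSII (1 - qP)
#'
#' \deqn{1 - q_P = 1 - (F_M' - F_S)/(F_M' - F_0')}
#' 0 means all PSII centres are open (excitation is drained as fast as it
#' arrives); 1 means all centres are closed and further excitation risks
#' reactive-oxygen generation. Values slightly outside `[0, 1]` from
#' measurement noise are clamped with a warning.
#'
#' @param FS steady-state fluorescence under actinic light.
#' @param FM_prime maximal fluorescence under actinic light.
#' @param F0_prime minimal fluorescence under actinic light (see
#'   [f0_prime()]).
#' @return 1 - qP in `[0, 1]`, vectorised.
#' @examples
#' one_minus_qp(FS = 0.3, FM_prime = 0.8, F0_prime = 0.3)  # 0: all open
#' one_minus_qp(FS = 0.8, FM_prime = 0.8, F0_prime = 0.3)  # 1: all closed
#' @export
one_minus_qp <- function(FS, FM_prime, F0_prime) {
  if (any(FM_prime <= F0_prime)) stop("require FM_prime > F0_prime")
  val <- 1 - (FM_prime - FS) / (FM_prime - F0_prime)
  if (any(val < 0 | val > 1)) {
    warning("1-qP outside [0,1]; clamped (measurement noise)")
    val <- pmin(pmax(val, 0), 1)
  }
  val
}

#' Append excitation-pressure columns to a time course
#'
#' Computes F0' and 1 - qP for a treatment time course. By default only
#' the measurement after the first treatment-light period is evaluated
#' (excitation pressure stays nearly constant through the remaining
#' treatment periods); `per_period = TRUE` fills every illuminated period.
#'
#' @param tc time course with columns `F0`, `FM`, `FS`, `FM_prime`,
#'   `FM_prime_2s`, `role`.
#' @param per_period compute for all illuminated periods instead of only
#'   the first treatment period.
#' @return `tc` with `f0_prime` and `one_minus_qp` columns added; the
#'   first-treatment-period value is also attached as attribute
#'   `one_minus_qp`.
#' @export
add_excitation_pressure <- function(tc, per_period = FALSE) {
  need <- c("F0", "FM", "FS", "FM_prime", "FM_prime_2s", "role")
  if (!all(need %in% names(tc)))
    stop("time course must contain columns: ", paste(need, collapse = ", "))
  rows <- if (per_period) which(tc$role %in% c("growth", "treatment", "recovery"))
          else which(tc$role == "treatment")[1]
  if (!length(rows) || anyNA(rows)) stop("no treatment period in time course")
  tc$f0_prime <- NA_real_
  tc$one_minus_qp <- NA_real_
  tc$f0_prime[rows] <- f0_prime(tc$F0[rows], tc$FM[rows], tc$FM_prime_2s[rows])
  tc$one_minus_qp[rows] <- one_minus_qp(tc$FS[rows], tc$FM_prime[rows],
                                        tc$f0_prime[rows])
  attr(tc, "one_minus_qp") <- tc$one_minus_qp[which(tc$role == "treatment")[1]]
  tc
}
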