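#' Influence of sustained NPQ on photochemical yield
#'
#' Sustained non-photochemical quenching persists through the 2 s dark
#' intervals that precede each yield measurement, depressing FV'2s/FM'2s
#' below what photoinactivation alone would give, but relaxes over the
#' terminal low-light recovery period (while repair stays blocked by
#' lincomycin). Its influence is estimated as the recovery-period yield
#' minus the final treatment-period yield, floored at zero.
#'
#' @param fv_fm_recovery FV'2s/FM'2s after the low-light recovery period.
#' @param fv_fm_treatment_end FV'2s/FM'2s after the final treatment period.
#' @return Non-negative scalar influence.
#' @examples
#' sustained_npq_influence(0.40, 0.35)  # 0.05
#' sustained_npq_influence(0.30, 0.35)  # 0
#' @export
sustained_npq_influence <- function(fv_fm_recovery, fv_fm_treatment_end) {
  stopifnot(fv_fm_recovery > 0, fv_fm_recovery < 1,
            fv_fm_treatment_end > 0, fv_fm_treatment_end < 1)
  max(0, fv_fm_recovery - fv_fm_treatment_end)
}

#' Correct a treatment time course for sustained NPQ
#'
#' Computes the sustained-NPQ influence from the terminal recovery period
#' versus the final treatment period and adds it to FV'2s/FM'2s of every
#' illuminated pre-recovery period (the dark period-1 anchor and the
#' recovery period itself are untouched). Corrected values are capped just
#' below 1; confidence intervals are left unchanged. The applied influence
#' is recorded in the `npq_influence` attribute.
#'
#' @param tc a treatment time course: data.frame with at least `period`,
#'   `fv_fm_2s` and a `role` column identifying `"treatment"` and
#'   `"recovery"` rows (as produced by [make_timecourse()] or
#'   [read_timecourse_csv()]).
#' @return The corrected time course with attribute `npq_influence`.
#' @export
apply_npq_correction <- function(tc) {
  stopifnot(is.data.frame(tc), all(c("period", "fv_fm_2s") %in% names(tc)))
  role <- tc$role
  if (is.null(role))
    stop("time course lacks a 'role' column identifying treatment/recovery periods")
  if (!any(role == "recovery"))
    stop("no recovery period in time course; either add the terminal ",
         "low-light period or bypass correction (the fit functions accept ",
         "npq_correct = FALSE)")
  rec <- tc$fv_fm_2s[which(role == "recovery")[1]]
  trt_idx <- which(role == "treatment")
  if (!length(trt_idx)) stop("no treatment periods in time course")
  trt_end <- tc$fv_fm_2s[max(trt_idx)]
  infl <- sustained_npq_influence(rec, trt_end)
  out <- tc
  lit <- which(role %in% c("growth", "treatment"))
  out$fv_fm_2s[lit] <- pmin(out$fv_fm_2s[lit] + infl, 1 - 1e-9)
  attr(out, "npq_influence") <- infl
  out
}
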