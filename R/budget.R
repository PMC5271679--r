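#' Electron-equivalent cost model for PSII maintenance
#'
#' Metabolic costs, in electron equivalents, to replace photoinactivated
#' PSII either by de novo synthesis of a complete complex (1.96e5 e- per
#' PSII) or by the repair cycle that recycles most subunits while
#' degrading and re-synthesising the PsbA and PsbD cores (5.77e3 e- per
#' PsbA+PsbD pair). ATP costs are folded in at 1.33 e- per ATP
#' (respiratory electron transport); the constant is carried for
#' reference only, the two costs are used as given.
#'
#' @param e_per_psii_synthesis e- equivalents per de novo PSII.
#' @param e_per_psbAD_repair e- equivalents per PsbA+PsbD turnover.
#' @param e_per_atp electrons per ATP (informational).
#' @return An object of class `"cost_model"`.
#' @export
cost_model <- function(e_per_psii_synthesis = 1.96e5,
                       e_per_psbAD_repair = 5.77e3,
                       e_per_atp = 1.33) {
  stopifnot(e_per_psii_synthesis > 0, e_per_psbAD_repair > 0, e_per_atp > 0)
  if (e_per_psii_synthesis <= e_per_psbAD_repair)
    stop("synthesis cost must exceed repair cost")
  structure(list(e_per_psii_synthesis = e_per_psii_synthesis,
                 e_per_psbAD_repair = e_per_psbAD_repair,
                 e_per_atp = e_per_atp), class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("PSII maintenance cost model (electron equivalents)\n")
  cat(sprintf("  de novo synthesis: %.3g e-/PSII\n", x$e_per_psii_synthesis))
  cat(sprintf("  PsbA+PsbD repair:  %.3g e-/(PsbA+PsbD)\n", x$e_per_psbAD_repair))
  cat(sprintf("  ATP conversion:    %.3g e-/ATP (informational)\n", x$e_per_atp))
  invisible(x)
}

#' PSII electron transport rate per complex
#'
#' \deqn{e^- \, PSII^{-1} s^{-1} = \sigma_{PSII}'2s \times q_P \times I}
#' with the irradiance I converted at 6.022e-3 quanta A^-2 s^-1 per
#' umol photons m^-2 s^-1 so that the cross section (A^2 quanta^-1)
#' cancels units.
#'
#' @param sigma_psii_2s effective absorption cross section, A^2 quanta^-1.
#' @param qp fraction of open PSII (1 minus excitation pressure), `[0, 1]`.
#' @param intensity irradiance, umol photons m^-2 s^-1.
#' @return Electrons per PSII per second, vectorised.
#' @examples
#' etr_per_psii(170.8, 0.5, 1200)  # ~617
#' @export
etr_per_psii <- function(sigma_psii_2s, qp, intensity) {
  stopifnot(all(sigma_psii_2s >= 0), all(qp >= 0 & qp <= 1),
            all(intensity >= 0))
  sigma_psii_2s * qp * intensity * quanta_A2_per_umol
}

#' PSII photoinactivation event rate
#'
#' The per-complex probability of photoinactivation per second: the target
#' size sigma_i (A^2 quanta^-1) times the treatment irradiance converted
#' to quanta A^-2 s^-1.
#'
#' @param sigma_i photoinactivation target size, A^2 quanta^-1.
#' @param intensity irradiance, umol photons m^-2 s^-1.
#' @return Inactivations PSII^-1 s^-1, vectorised.
#' @examples
#' inactivation_rate(1.23e-4, 1200)  # ~8.9e-4
#' @export
inactivation_rate <- function(sigma_i, intensity) {
  stopifnot(all(sigma_i >= 0), all(intensity >= 0))
  sigma_i * intensity * quanta_A2_per_umol
}

#' Cost-benefit budget for PSII maintenance
#'
#' Compares the photochemical return from a PSII (electron transport,
#' [etr_per_psii()]) with the ongoing electron-equivalent cost of
#' countering photoinactivation ([inactivation_rate()] times the repair or
#' synthesis cost). A strategy is viable while its margin (ETR minus cost
#' rate) stays positive.
#'
#' @param sigma_psii_2s effective absorption cross section, A^2 quanta^-1.
#' @param sigma_i photoinactivation target size, A^2 quanta^-1.
#' @param qp fraction of open PSII.
#' @param intensity irradiance(s), umol photons m^-2 s^-1.
#' @param costs a [cost_model()].
#' @return An object of class `"psii_budget"` (a data.frame): per
#'   intensity, `etr`, `inactivation_rate`, `repair_cost_rate`,
#'   `synthesis_cost_rate`, the margins, and viability flags.
#' @examples
#' b <- psii_budget(250, 1e-4, qp = 0.5, intensity = c(150, 1500))
#' b$repair_viable
#' @export
psii_budget <- function(sigma_psii_2s, sigma_i, qp, intensity,
                        costs = cost_model()) {
  stopifnot(inherits(costs, "cost_model"))
  k <- max(length(intensity), length(sigma_psii_2s), length(sigma_i),
           length(qp))
  intensity <- rep_len(intensity, k)
  sigma_psii_2s <- rep_len(sigma_psii_2s, k)
  sigma_i <- rep_len(sigma_i, k)
  qp <- rep_len(qp, k)
  etr <- etr_per_psii(sigma_psii_2s, qp, intensity)
  inact <- inactivation_rate(sigma_i, intensity)
  repair <- inact * costs$e_per_psbAD_repair
  synth <- inact * costs$e_per_psii_synthesis
  out <- data.frame(
    intensity = intensity, sigma_psii_2s = sigma_psii_2s,
    sigma_i = sigma_i, qp = qp,
    etr = etr, inactivation_rate = inact,
    repair_cost_rate = repair, synthesis_cost_rate = synth,
    repair_margin = etr - repair, synthesis_margin = etr - synth,
    repair_viable = etr - repair > 0, synthesis_viable = etr - synth > 0)
  structure(out, class = c("psii_budget", "data.frame"), costs = costs)
}

#' @export
print.psii_budget <- function(x, ...) {
  cat("PSII electron budget (e- PSII^-1 s^-1)\n")
  print.data.frame(
    x[, c("intensity", "etr", "inactivation_rate", "repair_cost_rate",
          "synthesis_cost_rate", "repair_viable", "synthesis_viable")],
    row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.psii_budget <- function(x, ...) {
  ylim <- range(0, x$etr, x$synthesis_cost_rate)
  plot(x$intensity, x$etr, type = "b", pch = 19, ylim = ylim,
       xlab = "treatment light (umol photons m^-2 s^-1)",
       ylab = "e- PSII^-1 s^-1",
       main = "PSII return vs maintenance cost", ...)
  ord <- order(x$intensity)
  polygon(c(x$intensity[ord], rev(x$intensity[ord])),
          c(x$synthesis_cost_rate[ord], numeric(nrow(x))),
          col = grDevices::adjustcolor("grey50", 0.4), border = NA)
  lines(x$intensity[ord], x$repair_cost_rate[ord], lwd = 3)
  legend("topleft", bty = "n", pch = c(19, NA, 15), lty = c(1, 1, NA),
         col = c("black", "black", "grey65"), lwd = c(1, 3, NA),
         legend = c("PSII electron transport", "repair cost (PsbA+PsbD)",
                    "de novo synthesis cost"))
  invisible(x)
}

#' @rdname psii_budget
#' @param x a `psii_budget`.
#' @param path file path.
#' @export
write_budget_csv <- function(x, path) {
  stopifnot(inherits(x, "psii_budget"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
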