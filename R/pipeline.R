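#' Read and write treatment time-course CSV files
#'
#' Long-format CSV, one row per protocol period, with the photophysiology
#' columns produced by [make_timecourse()]: `period`, `elapsed_s`,
#' `context`/`role`, `F0`, `FM`, `FS`, `FM_prime`, `sigma_psii_prime`,
#' `F0_prime_2s`, `FM_prime_2s`, `sigma_psii_2s`, `fv_fm_2s`,
#' `fv_fm_2s_ci95`, `species`, `growth_light`, `treat_colour`,
#' `treat_intensity`.
#'
#' @param tc a `treatment_timecourse` data.frame.
#' @param path file path.
#' @return Reading returns a `treatment_timecourse` with its protocol
#'   reconstructed from the metadata columns; writing returns the path.
#' @export
write_timecourse_csv <- function(tc, path) {
  write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("period", "fv_fm_2s", "fv_fm_2s_ci95")
  if (!all(need %in% names(df)))
    stop("time-course CSV missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$role) && !is.null(df$context)) df$role <- df$context
  bad <- !is.finite(df$fv_fm_2s) | df$fv_fm_2s <= 0 | df$fv_fm_2s >= 1
  if (any(bad))
    stop("invalid fv_fm_2s at row(s) ", paste(which(bad), collapse = ", "),
         " of ", path, " (must lie in (0,1))")
  proto <- NULL
  if (all(c("treat_intensity", "treat_colour", "growth_light") %in% names(df)))
    proto <- treatment_protocol(df$treat_intensity[1], df$treat_colour[1],
                                growth_light = df$growth_light[1])
  structure(df, class = c("treatment_timecourse", "data.frame"),
            protocol = proto)
}

#' Write a synthetic scenario to disk with its ground-truth manifest
#'
#' Emits the time-course CSV and a `manifest.json` recording the
#' generating parameters, so downstream fits can be checked against known
#' truth.
#'
#' @param preset a [scenario_preset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(preset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tc <- make_timecourse(preset)
  csv <- file.path(dir, paste0(preset$name, "_timecourse.csv"))
  write_timecourse_csv(tc, csv)
  manifest <- file.path(dir, "manifest.json")
  truth <- unclass(preset)
  truth$phi_i_psii <- preset$sigma_i / preset$sigma_psii_2s
  jsonlite::write_json(list(files = basename(csv), ground_truth = truth),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(timecourse = csv, manifest = manifest))
}

pipeline_known_keys <- c("input", "presets", "weighting", "npq_correction",
                         "costs", "outdir", "seed")

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_known_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(input = NULL, presets = NULL, weighting = "inverse_ci",
                   npq_correction = TRUE, costs = list(), outdir = ".",
                   seed = 1L)
  config <- modifyList(defaults, config)
  if (is.null(config$input) && is.null(config$presets))
    stop("config must supply 'input' CSV paths or synthetic 'presets'")
  if (!config$weighting %in% c("inverse_ci", "inverse_ci2", "none"))
    stop("weighting must be inverse_ci, inverse_ci2 or none")
  config
}

#' Run the photoinactivation analysis pipeline end-to-end
#'
#' Binds the package's stages together: load (or synthesise) treatment
#' time courses, apply the sustained-NPQ correction, fit sigma_i and
#' Phi_i PSII, compute excitation pressure, assemble the electron budget,
#' and write every stage's output as CSV plus a run log. Deterministic
#' under a fixed config and seed.
#'
#' @param config a list (or path to a YAML file) with keys:
#'   \describe{
#'     \item{`input`}{character vector of time-course CSV paths, and/or}
#'     \item{`presets`}{character vector of [scenario_preset()] names to
#'       synthesise,}
#'     \item{`weighting`}{`"inverse_ci"` (default), `"inverse_ci2"` or
#'       `"none"`,}
#'     \item{`npq_correction`}{logical, default TRUE,}
#'     \item{`costs`}{list of [cost_model()] overrides,}
#'     \item{`outdir`}{output directory,}
#'     \item{`seed`}{integer seed.}
#'   }
#'   Unknown keys are rejected.
#' @return Invisibly, a list with the fitted `decay_fit` objects, the
#'   pressure-augmented time courses, the `psii_budget` and the output
#'   paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  set.seed(config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "pipeline.log")
  logline <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = logfile, append = TRUE)
    message(msg)
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  logline("psinact %s | seed %d | config md5 %s",
          as.character(packageVersion("psinact")), config$seed,
          unname(tools::md5sum(tf)))
  unlink(tf)

  tcs <- list()
  for (p in config$input %||% character()) {
    logline("reading %s", p)
    tcs[[basename(p)]] <- read_timecourse_csv(p)
  }
  for (nm in config$presets %||% character()) {
    logline("synthesising preset %s", nm)
    tcs[[nm]] <- make_timecourse(scenario_preset(nm))
  }

  costs <- do.call(cost_model, config$costs)
  fits_sigma <- list(); fits_phi <- list(); budget_rows <- list()
  pressed <- list()
  for (nm in names(tcs)) {
    tc <- tcs[[nm]]
    proto <- attr(tc, "protocol")
    if (is.null(proto))
      stop("time course '", nm, "' lacks protocol metadata ",
           "(treat_intensity/treat_colour/growth_light columns)")
    fits_sigma[[nm]] <- fit_sigma_i(tc, proto, weighting = config$weighting,
                                    npq_correct = config$npq_correction)
    fits_phi[[nm]] <- fit_phi_i(tc, proto, weighting = config$weighting,
                                npq_correct = config$npq_correction)
    tcp <- add_excitation_pressure(tc)
    pressed[[nm]] <- tcp
    qp <- 1 - attr(tcp, "one_minus_qp")
    trt <- which(tc$role == "treatment")[1]
    budget_rows[[nm]] <- psii_budget(
      sigma_psii_2s = tc$sigma_psii_2s[trt],
      sigma_i = fits_sigma[[nm]]$rate, qp = qp,
      intensity = tc$treat_intensity[1], costs = costs)
    logline("%s: sigma_i = %.4g, Phi_i = %.4g, 1-qP = %.4g",
            nm, fits_sigma[[nm]]$rate, fits_phi[[nm]]$rate, 1 - qp)
  }

  paths <- c(
    sigma = file.path(config$outdir, "sigma_i_fits.csv"),
    phi = file.path(config$outdir, "phi_i_fits.csv"),
    pressure = file.path(config$outdir, "excitation_pressure.csv"),
    budget = file.path(config$outdir, "budget.csv"))
  write_decay_csv(fits_sigma, paths[["sigma"]], labels = names(tcs))
  write_decay_csv(fits_phi, paths[["phi"]], labels = names(tcs))
  pressure_df <- do.call(rbind, lapply(names(pressed), function(nm) {
    d <- as.data.frame(pressed[[nm]])
    cbind(treatment = nm, d)
  }))
  write.csv(pressure_df, paths[["pressure"]], row.names = FALSE)
  budget_df <- do.call(rbind, lapply(names(budget_rows), function(nm)
    cbind(treatment = nm, as.data.frame(budget_rows[[nm]]))))
  write.csv(budget_df, paths[["budget"]], row.names = FALSE)
  logline("wrote %s", paste(paths, collapse = ", "))

  invisible(list(sigma_i = fits_sigma, phi_i = fits_phi,
                 pressure = pressed, budget = budget_rows,
                 paths = paths, config = config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
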