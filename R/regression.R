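#' Confidence-interval-weighted linear regression
#'
#' Weighted least squares with each point weighted by the inverse of its
#' 95% CI half-width (weight = 1/CI; the convention used for the
#' photoinactivation regressions) or classically by 1/CI^2. Weights are
#' treated as relative: inference uses the weighted residual variance, as
#' in `lm`. With equal CIs the fit reduces to ordinary least squares.
#'
#' @param x predictor (e.g. treatment intensity or 1 - qP).
#' @param y response (e.g. sigma_i or Phi_i PSII estimates).
#' @param ci95 95% CI half-width of each `y` (> 0). Omit for equal weights.
#' @param weighting `"inverse_ci"` (default) or `"inverse_ci2"`.
#' @return An object of class `"ci_wls"`: `slope`, `intercept`, standard
#'   errors, 95% CI half-widths, p-values against zero, `r_squared`, `n`,
#'   `intercept_zero` (TRUE when the intercept is not distinguishable from
#'   zero at p > 0.05), the weights and the underlying `lm` fit.
#' @examples
#' f <- weighted_linear_fit(1:5, 2 * (1:5) + 1, ci95 = rep(0.1, 5))
#' coef(f)
#' @export
weighted_linear_fit <- function(x, y, ci95 = NULL,
                                weighting = c("inverse_ci", "inverse_ci2")) {
  weighting <- match.arg(weighting)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (diff(range(x)) <= 0) stop("degenerate predictor: all x values equal")
  w <- if (is.null(ci95)) rep(1, length(x)) else {
    stopifnot(length(ci95) == length(y), all(ci95 > 0))
    if (weighting == "inverse_ci") 1 / ci95 else 1 / ci95^2
  }
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  n <- length(x)
  tq <- qt(0.975, df = n - 2)
  structure(list(
    slope = co["x", "Estimate"], intercept = co["(Intercept)", "Estimate"],
    slope_se = co["x", "Std. Error"],
    intercept_se = co["(Intercept)", "Std. Error"],
    slope_ci95 = co["x", "Std. Error"] * tq,
    intercept_ci95 = co["(Intercept)", "Std. Error"] * tq,
    slope_p = co["x", "Pr(>|t|)"], intercept_p = co["(Intercept)", "Pr(>|t|)"],
    intercept_zero = co["(Intercept)", "Pr(>|t|)"] > 0.05,
    r_squared = sm$r.squared, n = n, weights = w, weighting = weighting,
    lm = fit), class = "ci_wls")
}

#' @export
print.ci_wls <- function(x, digits = 4, ...) {
  cat("CI-weighted linear regression\n")
  cat(sprintf("  slope     = %s +/- %s (SE), p = %.3g\n",
              format(x$slope, digits = digits),
              format(x$slope_se, digits = 3), x$slope_p))
  cat(sprintf("  intercept = %s +/- %s (SE), p = %.3g%s\n",
              format(x$intercept, digits = digits),
              format(x$intercept_se, digits = 3), x$intercept_p,
              if (x$intercept_zero) " [not significantly different from zero]"
              else ""))
  cat(sprintf("  R^2 = %.4f, n = %d, weighting = %s\n",
              x$r_squared, x$n, x$weighting))
  invisible(x)
}

#' @export
coef.ci_wls <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.ci_wls <- function(object, ...) {
  print(object)
  invisible(coef_table(object))
}

#' Tidy coefficient table from a weighted regression
#'
#' @param object a `ci_wls` fit.
#' @return data.frame with one row per coefficient: estimate, SE, 95% CI
#'   half-width, p-value.
#' @export
coef_table <- function(object) {
  stopifnot(inherits(object, "ci_wls"))
  data.frame(
    term = c("intercept", "slope"),
    estimate = c(object$intercept, object$slope),
    se = c(object$intercept_se, object$slope_se),
    ci95 = c(object$intercept_ci95, object$slope_ci95),
    p_value = c(object$intercept_p, object$slope_p))
}

#' @export
predict.ci_wls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) fitted(object$lm)
  else object$intercept + object$slope * newdata
}

#' Binary-grouping interaction test for weighted regressions
#'
#' Fits the weighted linear model `y ~ x * group` with a two-level
#' grouping factor (e.g. species, or low vs high growth light) and reports
#' whether the group shifts the line (group main effect) or changes its
#' slope (interaction term). Used to ask whether two treatment series
#' share a common regression.
#'
#' @inheritParams weighted_linear_fit
#' @param group two-level factor (or coercible) of the same length as `x`.
#' @return A list of class `"interaction_test"`: `p_interaction`,
#'   `p_group`, `interaction_coef` (slope difference), `group_coef`,
#'   coefficient table and the `lm` fit.
#' @export
interaction_test <- function(x, y, ci95 = NULL, group,
                             weighting = c("inverse_ci", "inverse_ci2")) {
  weighting <- match.arg(weighting)
  group <- factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly 2 levels (got ", nlevels(group), ")")
  if (any(table(group) < 3)) stop("each group needs at least 3 points")
  stopifnot(length(x) == length(y), length(group) == length(x))
  w <- if (is.null(ci95)) rep(1, length(x)) else {
    stopifnot(all(ci95 > 0))
    if (weighting == "inverse_ci") 1 / ci95 else 1 / ci95^2
  }
  fit <- lm(y ~ x * group, weights = w)
  co <- summary(fit)$coefficients
  int_row <- grep(":", rownames(co))
  grp_row <- setdiff(grep("group", rownames(co)), int_row)
  structure(list(
    p_interaction = co[int_row, "Pr(>|t|)"],
    p_group = co[grp_row, "Pr(>|t|)"],
    interaction_coef = co[int_row, "Estimate"],
    group_coef = co[grp_row, "Estimate"],
    coefficients = co, lm = fit), class = "interaction_test")
}

#' @export
print.interaction_test <- function(x, ...) {
  cat("Weighted linear model y ~ x * group\n")
  cat(sprintf("  group main effect: %.4g (p = %.3g)\n",
              x$group_coef, x$p_group))
  cat(sprintf("  interaction (slope difference): %.4g (p = %.3g)\n",
              x$interaction_coef, x$p_interaction))
  invisible(x)
}

#' Exponential growth rate from a fluorescence time series
#'
#' Cultures in exponential phase follow RFU_t = RFU_0 exp(mu t); mu (d^-1)
#' is estimated by linear regression of ln(RFU) on time.
#'
#' @param time elapsed time, days (strictly increasing, >= 3 points).
#' @param rfu relative fluorescence units (> 0).
#' @return An object of class `"growth_fit"`: `mu` (d^-1), `mu_se`,
#'   `mu_ci95`, `rfu0`, `r_squared`, `n` and the `lm` fit.
#' @examples
#' fit_exponential_growth(0:5, 100 * 2^(0:5))$mu  # ln 2
#' @export
fit_exponential_growth <- function(time, rfu) {
  stopifnot(length(time) == length(rfu))
  if (length(time) < 3) stop("need at least 3 points")
  if (any(rfu <= 0)) stop("RFU values must be positive")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  fit <- lm(log(rfu) ~ time)
  sm <- summary(fit)
  tq <- qt(0.975, df = length(time) - 2)
  structure(list(
    mu = coef(fit)[["time"]], mu_se = sm$coefficients["time", "Std. Error"],
    mu_ci95 = sm$coefficients["time", "Std. Error"] * tq,
    rfu0 = exp(coef(fit)[["(Intercept)"]]),
    r_squared = sm$r.squared, n = length(time), lm = fit),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth fit: mu = %.4g +/- %.3g d^-1 (95%% CI), R^2 = %.4f, n = %d\n",
              x$mu, x$mu_ci95, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) c(mu = object$mu, rfu0 = object$rfu0)
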