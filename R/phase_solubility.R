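#' Higuchi-Connors 1:1 stability constant from an A_L slope
#'
#' For a linear (A_L-type) phase-solubility diagram of a 1:1 complex the
#' slope obeys `slope = Kc * S0 / (1 + Kc * S0)`, so
#' `Kc = slope / (S0 * (1 - slope))`.
#'
#' @param slope fitted diagram slope, in `(0, 1)`.
#' @param s0 intrinsic guest solubility (M).
#' @param slope_se optional standard error of the slope; if given, the
#'   standard error of Kc is propagated by the delta method,
#'   `dKc/dslope = 1 / (S0 * (1 - slope)^2)`.
#' @return Kc in M^-1; with `slope_se`, a vector `c(kc, kc_se)`.
#' @examples
#' stability_constant(0.5, 1e-4)    # 1e4: Kc = 1/S0 at slope 1/2
#' @export
stability_constant <- function(slope, s0, slope_se = NULL) {
  if (!is.finite(slope) || slope <= 0 || slope >= 1)
    stop("the 1:1 A_L formula requires slope in (0, 1)", call. = FALSE)
  if (!is.finite(s0) || s0 <= 0)
    stop("intrinsic solubility must be positive", call. = FALSE)
  kc <- slope / (s0 * (1 - slope))
  if (is.null(slope_se)) return(kc)
  c(kc = kc, kc_se = slope_se / (s0 * (1 - slope)^2))
}

#' Binding free energy from an association constant
#'
#' `dG = -R T ln(Kc)` with `R = 8.31446 J mol^-1 K^-1`; `1 kcal = 4184 J`.
#'
#' @param kc association constant (M^-1), `> 0`.
#' @param temperature temperature (K), `> 0`.
#' @param unit `"kcal/mol"` or `"kJ/mol"`.
#' @return Molar free energy in the requested unit.
#' @examples
#' gibbs_from_kc(6025, 298)   # about -5.15 kcal/mol
#' @export
gibbs_from_kc <- function(kc, temperature = 298,
                          unit = c("kcal/mol", "kJ/mol")) {
  unit <- match.arg(unit)
  if (!is.finite(kc) || kc <= 0) stop("kc must be positive", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  dg_j <- -8.31446 * temperature * log(kc)
  if (unit == "kcal/mol") dg_j / 4184 else dg_j / 1000
}

#' Phase-solubility dataset
#'
#' @param cd_conc host (cyclodextrin) concentrations (M), non-negative and
#'   strictly increasing, at least three levels including 0.
#' @param solubility dissolved guest (M) at each host level, positive.
#' @param temperature K.
#' @return An object of class `phase_solubility_data`.
#' @export
phase_solubility_data <- function(cd_conc, solubility, temperature = 298) {
  cd_conc <- as.numeric(cd_conc)
  solubility <- as.numeric(solubility)
  if (length(cd_conc) != length(solubility))
    stop("cd_conc and solubility must have equal length", call. = FALSE)
  if (length(cd_conc) < 3L)
    stop("at least 3 concentration levels are required", call. = FALSE)
  if (any(cd_conc < 0) || any(diff(cd_conc) <= 0))
    stop("cd_conc must be non-negative and strictly increasing",
         call. = FALSE)
  if (any(solubility <= 0))
    stop("solubilities must be positive", call. = FALSE)
  structure(list(cd_conc = cd_conc, solubility = solubility,
                 temperature = temperature),
            class = "phase_solubility_data")
}

#' Fit a phase-solubility diagram
#'
#' Ordinary least squares of dissolved guest on host concentration.  The
#' diagram is classified `A_L` when the fit is linear (`r^2 >=
#' linearity_threshold`) with slope in `(0, 1)`; the 1:1 stability constant
#' is then computed by [stability_constant()] using the measured intrinsic
#' solubility `s0` when supplied (the preferred source), else the fitted
#' intercept, with its standard error propagated from the slope by the delta
#' method.
#'
#' @param data a [phase_solubility_data()] object (or a list/data.frame with
#'   `cd_conc` and `solubility`).
#' @param s0 measured intrinsic solubility (M), or `NULL` to use the
#'   intercept.
#' @param linearity_threshold minimum r^2 for the A_L class.
#' @return An object of class `phsol_fit` with fields `slope`, `slope_se`,
#'   `intercept`, `r_squared`, `diagram_class`, `kc`, `kc_se`, `delta_g`
#'   (kcal/mol), `s0_used`, `temperature`, `model` (the underlying [lm()]).
#' @examples
#' d <- gen_phase_solubility(kc = 6031, s0 = 2e-5, cv = 0, seed = 1)
#' fit_phase_solubility(d, s0 = 2e-5)
#' @export
fit_phase_solubility <- function(data, s0 = NULL, linearity_threshold = 0.99) {
  if (!inherits(data, "phase_solubility_data"))
    data <- phase_solubility_data(data$cd_conc, data$solubility,
                                  if (!is.null(data$temperature))
                                    data$temperature else 298)
  fit <- stats::lm(solubility ~ cd_conc,
                   data = data.frame(cd_conc = data$cd_conc,
                                     solubility = data$solubility))
  sm <- suppressWarnings(summary(fit))   # noiseless data: perfect-fit note
  slope <- unname(stats::coef(fit)[2L])
  slope_se <- sm$coefficients[2L, 2L]
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- sm$r.squared
  is_al <- is.finite(r2) && r2 >= linearity_threshold &&
    slope > 0 && slope < 1
  kc <- kc_se <- dg <- NA_real_
  s0_used <- if (!is.null(s0)) s0 else intercept
  if (is_al && is.finite(s0_used) && s0_used > 0) {
    k <- stability_constant(slope, s0_used, slope_se)
    kc <- unname(k[1L]); kc_se <- unname(k[2L])
    dg <- gibbs_from_kc(kc, data$temperature)
  }
  structure(list(slope = slope, slope_se = slope_se, intercept = intercept,
                 r_squared = r2,
                 diagram_class = if (is_al) "A_L" else "nonlinear",
                 kc = kc, kc_se = kc_se, delta_g = dg, s0_used = s0_used,
                 temperature = data$temperature, data = data, model = fit),
            class = "phsol_fit")
}

#' @export
print.phsol_fit <- function(x, ...) {
  cat("Phase-solubility diagram fit (Higuchi-Connors)\n")
  cat(sprintf("  slope     = %.5g +/- %.2g\n", x$slope, x$slope_se))
  cat(sprintf("  intercept = %.5g M\n", x$intercept))
  cat(sprintf("  r^2       = %.6f   class: %s\n", x$r_squared,
              x$diagram_class))
  if (is.finite(x$kc))
    cat(sprintf("  Kc = %.4g M^-1 (SE %.2g), dG(%g K) = %.3f kcal/mol\n",
                x$kc, x$kc_se, x$temperature, x$delta_g))
  invisible(x)
}

#' @export
summary.phsol_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying linear model:\n")
  print(summary(object$model))
  invisible(object)
}

#' @export
coef.phsol_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope, kc = object$kc)
}

#' @export
predict.phsol_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$model))
  if (is.numeric(newdata)) newdata <- data.frame(cd_conc = newdata)
  stats::predict(object$model, newdata = newdata, ...)
}

#' @export
plot.phsol_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$cd_conc * 1e3, d$solubility * 1e3,
                 xlab = "[CD] (mM)", ylab = "dissolved guest (mM)", ...)
  graphics::abline(x$intercept * 1e3, x$slope, col = "red")
  invisible(x)
}

#' @export
residuals.phsol_fit <- function(object, ...) stats::residuals(object$model)
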