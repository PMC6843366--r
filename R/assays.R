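#' Cell viability percentage (MTT assay)
#'
#' `viability (%) = 100 * Abs_treated / Abs_control`.
#'
#' @param abs_treated absorbance of treated wells, `>= 0` (vectorized).
#' @param abs_control absorbance of untreated control wells, `> 0`.
#' @return Percent viability.
#' @export
viability_percent <- function(abs_treated, abs_control) {
  if (any(abs_control <= 0))
    stop("control absorbance must be positive", call. = FALSE)
  if (any(abs_treated < 0))
    stop("treated absorbance must be non-negative", call. = FALSE)
  100 * abs_treated / abs_control
}

#' LDH release percentage
#'
#' Lactate-dehydrogenase leakage as a percentage of the total releasable
#' signal; values above the total are allowed but flagged.
#'
#' @param released measured LDH signal, `>= 0`.
#' @param total total (full-lysis) LDH signal, `> 0`.
#' @return Percent release, with attribute `over_total` when any value
#'   exceeds 100.
#' @export
ldh_release_percent <- function(released, total) {
  if (any(total <= 0)) stop("total signal must be positive", call. = FALSE)
  if (any(released < 0)) stop("released signal must be non-negative",
                              call. = FALSE)
  pct <- 100 * released / total
  if (any(released > total))
    warning("released signal exceeds total; percentage above 100",
            call. = FALSE)
  structure(pct, over_total = any(released > total))
}

#' Permeation sampling series (Franz-type diffusion cell)
#'
#' @param times sampling times (h), strictly increasing.
#' @param sample_conc guest concentration in each withdrawn sample
#'   (mass/volume, e.g. ug/mL), `>= 0`.
#' @param receptor_volume receptor compartment volume (mL).
#' @param sample_volume withdrawn-and-replaced aliquot volume (mL),
#'   below `receptor_volume`.
#' @param dose guest amount applied to the donor (same mass unit as
#'   `sample_conc * volume`).
#' @return An object of class `permeation_series`.
#' @export
permeation_series <- function(times, sample_conc, receptor_volume = 4.5,
                              sample_volume = 0.5, dose = NA_real_) {
  if (length(times) != length(sample_conc))
    stop("one concentration per time point required", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (sample_volume >= receptor_volume)
    stop("sample_volume must be below receptor_volume", call. = FALSE)
  if (any(sample_conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  structure(list(times = as.numeric(times),
                 sample_conc = as.numeric(sample_conc),
                 receptor_volume = receptor_volume,
                 sample_volume = sample_volume, dose = dose),
            class = "permeation_series")
}

#' Cumulative permeated amount with sampling-dilution correction
#'
#' Each withdrawal removes `C_i * V_sample` of guest and is replaced with
#' fresh receptor phase, so the cumulative amount at sampling `n` is
#' `Q_n = C_n * V_receptor + sum_{i<n} C_i * V_sample`.
#'
#' @param series a [permeation_series()].
#' @return Data frame with `time`, `cumulative_amount` and, when the dose
#'   is known, `percent_of_dose`.
#' @export
cumulative_permeation <- function(series) {
  stopifnot(inherits(series, "permeation_series"))
  C <- series$sample_conc
  removed <- c(0, cumsum(C * series$sample_volume)[-length(C)])
  Q <- C * series$receptor_volume + removed
  out <- data.frame(time = series$times, cumulative_amount = Q)
  if (is.finite(series$dose) && series$dose > 0)
    out$percent_of_dose <- 100 * Q / series$dose
  out
}

#' Mucosal accumulation percentage
#'
#' Amount recovered from the tissue as a percentage of the applied dose,
#' optionally corrected for the extraction recovery factor of the assay
#' (97% w/w for the validated workup).
#'
#' @param recovered amount recovered from the tissue.
#' @param dose applied dose (same unit).
#' @param recovery_factor fractional extraction recovery; `1` disables the
#'   correction.
#' @return Percent of dose accumulated in the mucosa.
#' @export
mucosal_accumulation_percent <- function(recovered, dose,
                                         recovery_factor = 0.97) {
  if (dose <= 0) stop("dose must be positive", call. = FALSE)
  if (recovery_factor <= 0 || recovery_factor > 1)
    stop("recovery_factor must be in (0, 1]", call. = FALSE)
  100 * (recovered / recovery_factor) / dose
}

#' HPLC calibration with LOD/LOQ by signal-to-noise
#'
#' Least-squares calibration line over the standards; detection and
#' quantitation limits follow the pharmacopoeial signal-to-noise
#' convention, `LOD = 3 * noise_sd / slope` and `LOQ = 10 * noise_sd /
#' slope`, so `LOQ / LOD = 10/3` exactly.
#'
#' @param concentrations standard concentrations (ug/mL), `>= 5` levels.
#' @param responses detector responses (peak area).
#' @param noise_sd baseline noise standard deviation in response units.
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `lod`, `loq`, `noise_sd`, `model`.
#' @export
fit_calibration <- function(concentrations, responses, noise_sd) {
  if (length(concentrations) != length(responses))
    stop("one response per concentration required", call. = FALSE)
  if (length(concentrations) < 5L)
    stop("at least 5 calibration levels required", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  fit <- stats::lm(responses ~ concentrations)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive", call. = FALSE)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 noise_sd = noise_sd,
                 lod = 3 * noise_sd / slope,
                 loq = 10 * noise_sd / slope,
                 model = fit),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("HPLC calibration\n")
  cat(sprintf("  response = %.5g + %.5g * conc, r^2 = %.6f\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  LOD = %.4g, LOQ = %.4g (S/N = 3 and 10)\n", x$lod, x$loq))
  invisible(x)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$model))
  if (is.numeric(newdata)) newdata <- data.frame(concentrations = newdata)
  stats::predict(object$model, newdata = newdata, ...)
}
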