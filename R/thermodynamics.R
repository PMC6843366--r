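R_GAS <- 8.31446  # J mol^-1 K^-1

#' Two-state population ratio of a six-band O-H deconvolution
#'
#' For the hydroxyl-stretching analysis of a cyclodextrin complex the six
#' sub-bands split into a weakly hydrogen-bonded class (the two
#' highest-wavenumber components) and a hydrogen-bonded class (the four
#' lower ones); the population ratio is
#' `R = (I1 + I2) / (I3 + I4 + I5 + I6)` on the percent areas taken in
#' descending-center order.
#'
#' @param deconv a [fit_bands()] result with exactly six peaks.
#' @return The dimensionless ratio `R`.
#' @export
population_ratio <- function(deconv) {
  stopifnot(inherits(deconv, "deconvolution"))
  if (nrow(deconv$peaks) != 6L)
    stop("the two-state O-H analysis requires exactly six sub-bands",
         call. = FALSE)
  I <- percent_areas(deconv)               # descending center: I1 first
  den <- sum(I[3:6])
  if (den == 0) stop("hydrogen-bonded class has zero area", call. = FALSE)
  sum(I[1:2]) / den
}

#' van 't Hoff fit of a two-state population ratio
#'
#' Ordinary least squares of `ln R` on `1/T`.  The hydrogen-bond rupture
#' enthalpy is reported as the positive magnitude `|slope| * R_gas`
#' (weakly bonded population grows with temperature, so the slope against
#' `1/T` is negative); the entropy is `intercept * R_gas` with its fitted
#' sign.  Standard errors come from the regression.
#'
#' @param temperatures K, distinct, `>= 3` values.
#' @param ratios population ratios `R > 0`, one per temperature.
#' @return An object of class `vant_hoff`: `delta_h`, `delta_h_se` (J/mol),
#'   `delta_s`, `delta_s_se` (J/mol/K), `fit_r_squared`, `temperatures`,
#'   `ratios`, `model`.
#' @export
vant_hoff_fit <- function(temperatures, ratios) {
  temperatures <- as.numeric(temperatures)
  ratios <- as.numeric(ratios)
  if (length(temperatures) != length(ratios))
    stop("one ratio per temperature required", call. = FALSE)
  if (length(temperatures) < 3L)
    stop("at least 3 temperatures required", call. = FALSE)
  if (any(temperatures <= 0) || anyDuplicated(temperatures))
    stop("temperatures must be positive and distinct", call. = FALSE)
  if (any(ratios <= 0))
    stop("ratios must be positive", call. = FALSE)
  d <- data.frame(inv_t = 1 / temperatures, ln_r = log(ratios))
  fit <- stats::lm(ln_r ~ inv_t, data = d)
  sf <- suppressWarnings(summary(fit))   # exact data: perfect-fit note
  sm <- sf$coefficients
  structure(list(delta_h = abs(sm[2L, 1L]) * R_GAS,
                 delta_h_se = sm[2L, 2L] * R_GAS,
                 delta_s = sm[1L, 1L] * R_GAS,
                 delta_s_se = sm[1L, 2L] * R_GAS,
                 fit_r_squared = sf$r.squared,
                 temperatures = temperatures, ratios = ratios, model = fit),
            class = "vant_hoff")
}

#' @export
print.vant_hoff <- function(x, ...) {
  cat("van 't Hoff two-state fit (ln R vs 1/T)\n")
  cat(sprintf("  dH_HB = %.0f +/- %.0f J/mol\n", x$delta_h, x$delta_h_se))
  cat(sprintf("  dS_HB = %.2f +/- %.2f J/mol/K\n", x$delta_s, x$delta_s_se))
  cat(sprintf("  r^2   = %.5f over %d temperatures (%g-%g K)\n",
              x$fit_r_squared, length(x$temperatures),
              min(x$temperatures), max(x$temperatures)))
  invisible(x)
}

#' @export
coef.vant_hoff <- function(object, ...) {
  c(delta_h = object$delta_h, delta_s = object$delta_s)
}

#' @export
plot.vant_hoff <- function(x, ...) {
  graphics::plot(1 / x$temperatures, log(x$ratios),
                 xlab = "1/T (1/K)", ylab = "ln R", ...)
  graphics::abline(x$model, col = "red")
  invisible(x)
}

#' Locate an isosbestic point in a spectral series
#'
#' Area-normalizes every member spectrum, then returns the axis point where
#' the across-condition standard deviation of intensity is smallest.  The
#' spread is that minimum relative to the median across-condition SD; the
#' point is flagged as a true isosbestic crossing when the spread is below
#' 0.05.  A two-state system whose spectra are mixtures of two fixed basis
#' spectra crosses at a single point, so the SD dips to (numerically) zero
#' there.  Only axis points carrying appreciable intensity (mean above 10%
#' of the band maximum) are candidates: in the empty baseline regions the
#' SD is trivially small without any crossing.
#'
#' @param series a [spectral_series()] with at least three spectra.
#' @return List with `center` (axis value), `spread`, `present` (logical),
#'   and `degenerate` (`TRUE` when the spectra are identical and every
#'   point ties).
#' @export
find_isosbestic <- function(series) {
  stopifnot(inherits(series, "cd_series"))
  if (length(series$spectra) < 3L)
    stop("at least 3 spectra required", call. = FALSE)
  Y <- vapply(series$spectra,
              function(s) normalize(s, "unit-area")$intensity,
              numeric(length(series$axis)))
  # refine on a 10x linearly interpolated grid: interpolation commutes
  # with mixing, so a two-state crossing survives exactly between samples
  fine <- seq(series$axis[1L], series$axis[length(series$axis)],
              length.out = (length(series$axis) - 1L) * 10L + 1L)
  Y <- apply(Y, 2L, function(col)
    stats::approx(series$axis, col, xout = fine)$y)
  series <- list(axis = fine)
  mu <- rowMeans(Y)
  cand <- which(mu >= 0.1 * max(mu))
  sds <- apply(Y[cand, , drop = FALSE], 1L, stats::sd)
  med <- stats::median(sds)
  if (med == 0 || !is.finite(med)) {
    return(list(center = NA_real_, spread = NA_real_, present = FALSE,
                degenerate = TRUE))
  }
  i <- which.min(sds)
  spread <- sds[i] / med
  list(center = series$axis[cand[i]], spread = spread,
       present = spread < 0.05, degenerate = FALSE)
}
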