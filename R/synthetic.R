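#' Synthetic phase-solubility dataset
#'
#' Generates an A_L-type isotherm `S(c) = s0 + c * Kc*s0 / (1 + Kc*s0)`
#' with multiplicative Gaussian noise of coefficient of variation `cv`.
#' Defaults reproduce the study conditions: a 0-9 mM host grid in 1 mM
#' steps around an association constant of ~6e3 M^-1 and intrinsic
#' solubility 2e-5 M.
#'
#' @param kc generating association constant (M^-1).
#' @param s0 intrinsic guest solubility (M).
#' @param cd_grid host concentrations (M).
#' @param cv relative noise (0 for the exact line).
#' @param seed integer seed.
#' @param temperature K.
#' @return A [phase_solubility_data()] object.
#' @export
gen_phase_solubility <- function(kc = 6031, s0 = 2e-5,
                                 cd_grid = seq(0, 9e-3, by = 1e-3),
                                 cv = 0.02, seed = 1L, temperature = 298) {
  if (kc <= 0 || s0 <= 0) stop("kc and s0 must be positive", call. = FALSE)
  slope <- kc * s0 / (1 + kc * s0)
  s <- s0 + slope * cd_grid
  if (cv > 0)
    s <- s * (1 + with_seed(seed, stats::rnorm(length(s), 0, cv)))
  phase_solubility_data(cd_grid, pmax(s, s0 * 1e-3),
                        temperature = temperature)
}

#' Molar absorptivity shape from Gaussian bumps
#'
#' Evaluates a sum-of-Gaussians absorptivity spectrum on a wavelength grid.
#'
#' @param wavelengths nm grid.
#' @param spec data frame with `center` (nm), `width` (nm) and `height`
#'   (M^-1 cm^-1), one row per bump.
#' @return Numeric absorptivity vector.
#' @export
epsilon_shape <- function(wavelengths, spec) {
  y <- numeric(length(wavelengths))
  for (i in seq_len(nrow(spec)))
    y <- y + spec$height[i] *
      exp(-(wavelengths - spec$center[i])^2 / (2 * spec$width[i]^2))
  y
}

#' Default absorptivity shapes for the titration generator
#'
#' Distinct Gaussian-shaped molar absorptivity spectra for the free guest
#' (270 nm) and the inclusion complex (282 nm, hyperchromic), on the scale
#' of a quinone chromophore.
#'
#' @return Named list of data frames accepted by [gen_titration()].
#' @export
default_epsilon_specs <- function() {
  list(G = data.frame(center = 270, width = 25, height = 15000),
       complex = data.frame(center = 282, width = 28, height = 18500))
}

#' Synthetic multiwavelength titration dataset
#'
#' Speciates each titration point under `model`, applies Beer-Lambert with
#' Gaussian-bump absorptivity spectra, and adds i.i.d. additive absorbance
#' noise.  Defaults emulate the UV-Vis study conditions: guest total
#' 4.43e-5 M held constant while the host steps through 0 plus the seven
#' levels 4.43e-5 ... 2.21e-3 M, on a 200-400 nm grid.
#'
#' @param model a [binding_model()]; default 1:1 with `log10 beta =
#'   log10(6025)`.
#' @param epsilon_specs list of data frames (`center`, `width`, `height`
#'   in nm, nm, M^-1 cm^-1), one per absorbing species in model order.
#' @param g_tot guest total (M).
#' @param h_grid host totals (M); must include 0.
#' @param wavelengths nm grid.
#' @param noise_sd additive absorbance noise SD.
#' @param seed integer seed.
#' @param path_length cm.
#' @return A [titration_data()] object with attribute `true_epsilon`.
#' @export
gen_titration <- function(model = binding_model(1, 1, log10(6025)),
                          epsilon_specs = default_epsilon_specs(),
                          g_tot = 4.43e-5,
                          h_grid = c(0, 4.43e-5, 8.86e-5, 1.33e-4, 2.21e-4,
                                     4.43e-4, 6.64e-4, 2.21e-3),
                          wavelengths = seq(200, 400, by = 2),
                          noise_sd = 0.002, seed = 1L, path_length = 1) {
  n_abs <- sum(model$species$absorbing)
  if (length(epsilon_specs) != n_abs)
    stop("one epsilon spec per absorbing species required", call. = FALSE)
  E <- t(vapply(epsilon_specs, function(sp) epsilon_shape(wavelengths, sp),
                numeric(length(wavelengths))))
  if (any(E < 0)) stop("absorptivity shapes must be non-negative",
                       call. = FALSE)
  shell <- titration_data(g_tot, h_grid, wavelengths,
                          matrix(0, length(h_grid), length(wavelengths)),
                          path_length)
  A <- predict_absorbance(model, E, shell)
  if (noise_sd > 0)
    A <- A + with_seed(seed, matrix(stats::rnorm(length(A), 0, noise_sd),
                                    nrow(A)))
  out <- titration_data(g_tot, h_grid, wavelengths, A, path_length)
  attr(out, "true_epsilon") <- E
  out
}

#' Default six-component O-H sub-band template
#'
#' Centers follow the canonical assignment scheme of the hydroxyl envelope
#' of a hydroxypropylated cyclodextrin complex (3525, 3439, 3360, 3277,
#' 3191, 3084 cm^-1); the two highest-wavenumber bands form the weakly
#' hydrogen-bonded class.  Widths are chosen so the six second-derivative
#' minima stay resolvable.
#'
#' @return Data frame with `center`, `sigma`, `gamma`, `class`
#'   (1 = weakly bonded, 2 = hydrogen bonded) and within-class area
#'   proportion `prop`.
#' @export
oh_subband_template <- function() {
  data.frame(center = c(3525, 3439, 3360, 3277, 3191, 3084),
             sigma = c(28, 30, 30, 30, 30, 28),
             gamma = c(8, 8, 8, 8, 8, 8),
             class = c(1L, 1L, 2L, 2L, 2L, 2L),
             prop = c(0.45, 0.55, 0.30, 0.25, 0.25, 0.20))
}

#' Synthetic temperature series of O-H envelopes
#'
#' Builds, at each temperature, a unit-total-area envelope of six Voigt
#' sub-bands whose class populations follow a two-state van 't Hoff law:
#' `ln R(T) = -delta_h / (R_gas T) + delta_s / R_gas` with
#' `w_free = R / (1 + R)` (the magnitude convention: the weakly bonded
#' population grows with temperature).  Within-class proportions stay
#' fixed, so the series is an exact two-basis mixture and exhibits an
#' isosbestic point.  Noise is multiplicative per point.
#'
#' @param subbands template data frame (see [oh_subband_template()]).
#' @param delta_h hydrogen-bond rupture enthalpy (J/mol), positive.
#' @param delta_s entropy (J/mol/K).
#' @param temperatures K.
#' @param noise relative multiplicative noise.
#' @param seed integer seed.
#' @param axis wavenumber grid (cm^-1).
#' @return A [spectral_series()] with temperature as the condition, plus
#'   attributes `true_ratio` (R per temperature) and `basis` (the two
#'   unit-area class spectra).
#' @export
gen_oh_series <- function(subbands = oh_subband_template(),
                          delta_h = 10596, delta_s = 35.9,
                          temperatures = seq(250, 340, length.out = 10),
                          noise = 0.01, seed = 1L,
                          axis = seq(3000, 3800, by = 4)) {
  stopifnot(nrow(subbands) == 6L, all(sort(unique(subbands$class)) ==
                                        c(1L, 2L)))
  if (any(tapply(subbands$prop, subbands$class, sum) <= 0))
    stop("each class needs positive area", call. = FALSE)
  basis <- lapply(1:2, function(cl) {
    rows <- subbands[subbands$class == cl, ]
    w <- rows$prop / sum(rows$prop)
    y <- numeric(length(axis))
    for (i in seq_len(nrow(rows)))
      y <- y + voigt_profile(axis, rows$center[i], rows$sigma[i],
                             rows$gamma[i], w[i])
    y
  })
  lnR <- -delta_h / (R_GAS * temperatures) + delta_s / R_GAS
  ratio <- exp(lnR)
  w_free <- ratio / (1 + ratio)
  noise_mat <- if (noise > 0)
    with_seed(seed, matrix(stats::rnorm(length(axis) * length(temperatures),
                                        0, noise), length(axis)))
  else matrix(0, length(axis), length(temperatures))
  spectra <- lapply(seq_along(temperatures), function(i) {
    y <- w_free[i] * basis[[1L]] + (1 - w_free[i]) * basis[[2L]]
    y <- pmax(y * (1 + noise_mat[, i]), 0)
    spectrum_trace(axis, y, modality = "FTIR-ATR",
                   temperature = temperatures[i])
  })
  out <- spectral_series(spectra, temperatures)
  attr(out, "true_ratio") <- ratio
  attr(out, "basis") <- basis
  out
}

#' Synthetic DOSY diffusion measurement
#'
#' Speciates a 1:1 (or richer) system at the given totals, computes the
#' bound guest fraction, and returns the fast-exchange average
#' `D_obs = (1 - f) D_free + f D_complex` with optional relative noise on
#' the observed value.  Default scales follow the DOSY study: free guest
#' diffusion 2.69e-10 m^2/s at 14 mM equimolar totals.
#'
#' @param kc association constant (M^-1).
#' @param d_free free-guest diffusion (m^2/s).
#' @param d_complex bound-guest diffusion (m^2/s), below `d_free`.
#' @param h_tot,g_tot totals (M).
#' @param noise relative noise on `D_obs`.
#' @param seed integer seed.
#' @return A [diffusion_measurement()] with attribute `true_f`.
#' @export
gen_diffusion <- function(kc = 6025, d_free = 2.69e-10,
                          d_complex = 1.30e-10, h_tot = 1.4e-2,
                          g_tot = 1.4e-2, noise = 0, seed = 1L) {
  if (kc <= 0) stop("kc must be positive", call. = FALSE)
  if (d_complex >= d_free)
    stop("d_complex must be below d_free", call. = FALSE)
  st <- solve_speciation(binding_model(1, 1, log10(kc)), h_tot, g_tot)
  f <- (g_tot - st$free_g) / g_tot
  d_obs <- (1 - f) * d_free + f * d_complex
  if (noise > 0)
    d_obs <- d_obs * (1 + with_seed(seed, stats::rnorm(1, 0, noise)))
  out <- diffusion_measurement(d_free, d_obs, d_complex, h_tot, g_tot)
  attr(out, "true_f") <- f
  out
}
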