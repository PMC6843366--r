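#' Chemical-shift displacement table
#'
#' Per-proton complexation-induced shifts `delta_delta = delta_complex -
#' delta_free`; an all-positive table is flagged as a downfield displacement
#' (the signature of guest protons moving near electronegative atoms of the
#' host cavity rim).
#'
#' @param labels proton labels.
#' @param delta_free,delta_complex chemical shifts (ppm) of the free and
#'   complexed guest, matching `labels`.
#' @return An object of class `shift_table`: data frame plus a `downfield`
#'   attribute.
#' @examples
#' shift_displacements(c("1", "2"), c(3.48, 1.46), c(3.52, 1.49))
#' @export
shift_displacements <- function(labels, delta_free, delta_complex) {
  if (length(labels) != length(delta_free) ||
      length(labels) != length(delta_complex))
    stop("labels, delta_free, delta_complex must match in length",
         call. = FALSE)
  tab <- data.frame(proton = as.character(labels),
                    delta_free = as.numeric(delta_free),
                    delta_complex = as.numeric(delta_complex))
  tab$delta_delta <- tab$delta_complex - tab$delta_free
  structure(tab, class = c("shift_table", "data.frame"),
            downfield = all(tab$delta_delta > 0))
}

#' @export
print.shift_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  cat(if (isTRUE(attr(x, "downfield")))
    "all protons downfield shifted\n" else "not uniformly downfield\n")
  invisible(x)
}

#' Diffusion measurement for a fast-exchange two-site system
#'
#' @param d_free_guest diffusion coefficient of the free guest (m^2/s).
#' @param d_obs_guest observed (population-averaged) guest diffusion in the
#'   mixture (m^2/s).
#' @param d_complex diffusion of the fully bound guest, usually approximated
#'   by the host/complex diffusion (m^2/s); must be below `d_free_guest`.
#' @param h_tot,g_tot optional totals (M) for [kc_from_diffusion()].
#' @return An object of class `diffusion_measurement`.
#' @export
diffusion_measurement <- function(d_free_guest, d_obs_guest, d_complex,
                                  h_tot = NA_real_, g_tot = NA_real_) {
  if (any(c(d_free_guest, d_obs_guest, d_complex) <= 0))
    stop("diffusion coefficients must be positive", call. = FALSE)
  if (d_complex >= d_free_guest)
    stop("d_complex must be below d_free_guest", call. = FALSE)
  structure(list(d_free_guest = d_free_guest, d_obs_guest = d_obs_guest,
                 d_complex = d_complex, h_tot = h_tot, g_tot = g_tot),
            class = "diffusion_measurement")
}

#' Bound guest fraction from DOSY diffusion coefficients
#'
#' Under fast exchange the observed diffusion coefficient is the
#' population-weighted average of the free and bound values, so
#' `f = (D_free - D_obs) / (D_free - D_complex)`.  Values outside `[0, 1]`
#' (possible with noisy inputs) are clipped and flagged.
#'
#' @param meas a [diffusion_measurement()].
#' @return The bound fraction, with attribute `clipped` when the raw value
#'   fell outside `[0, 1]`.
#' @export
bound_fraction <- function(meas) {
  stopifnot(inherits(meas, "diffusion_measurement"))
  f <- (meas$d_free_guest - meas$d_obs_guest) /
    (meas$d_free_guest - meas$d_complex)
  clipped <- f < 0 || f > 1
  if (clipped)
    warning("bound fraction outside [0, 1]; clipped", call. = FALSE)
  structure(min(max(f, 0), 1), clipped = clipped)
}

#' 1:1 association constant from a bound fraction
#'
#' Inverts the 1:1 mass-action law: with bound guest `b = f * g_tot`,
#' `Kc = b / ((g_tot - b) * (h_tot - b))`.
#'
#' @param f bound guest fraction, strictly inside `(0, 1)`.
#' @param h_tot,g_tot totals (M), positive, with `f * g_tot < h_tot`.
#' @return Kc in M^-1.
#' @export
kc_from_diffusion <- function(f, h_tot, g_tot) {
  f <- as.numeric(f)
  if (!is.finite(f) || f <= 0 || f >= 1)
    stop("f must lie strictly inside (0, 1)", call. = FALSE)
  if (h_tot <= 0 || g_tot <= 0) stop("totals must be positive",
                                     call. = FALSE)
  b <- f * g_tot
  if (b >= h_tot)
    stop("bound guest exceeds total host; 1:1 inversion impossible",
         call. = FALSE)
  b / ((g_tot - b) * (h_tot - b))
}
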