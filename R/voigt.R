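# Faddeeva function w(z) = exp(-z^2) erfc(-iz), Im(z) >= 0, by Weideman's
# rational approximation (SIAM Rev. 36, 1994).  N = 32 poles gives close to
# machine precision on the upper half-plane; coefficients are computed once.
.weideman_env <- new.env(parent = emptyenv())

weideman_coefs <- function(N = 32L) {
  key <- as.character(N)
  if (!is.null(.weideman_env[[key]])) return(.weideman_env[[key]])
  M <- 2L * N
  M2 <- 2L * M
  k <- seq.int(-M + 1L, M - 1L)
  L <- sqrt(N / sqrt(2))
  theta <- k * pi / M
  t <- L * tan(theta / 2)
  f <- exp(-t^2) * (L^2 + t^2)
  f <- c(0, f)
  # fftshift then FFT: Fourier coefficients of f on the mapped circle
  half <- ceiling(length(f) / 2)
  fs <- c(f[(half + 1L):length(f)], f[1:half])
  a <- Re(stats::fft(fs)) / M2
  a <- rev(a[2:(N + 1L)])
  out <- list(a = a, L = L)
  .weideman_env[[key]] <- out
  out
}

#' Faddeeva (complex probability) function
#'
#' Computes `w(z) = exp(-z^2) * erfc(-iz)` for `Im(z) >= 0`, the kernel of
#' the Voigt line shape.
#'
#' @param z complex vector with non-negative imaginary part.
#' @return Complex vector `w(z)`.
#' @keywords internal
faddeeva_w <- function(z) {
  cf <- weideman_coefs()
  L <- cf$L
  a <- cf$a
  iz <- 1i * z
  Z <- (L + iz) / (L - iz)
  p <- rep(0 + 0i, length(z))
  for (ak in a) p <- p * Z + ak          # Horner on the mapped variable
  2 * p / (L - iz)^2 + (1 / sqrt(pi)) / (L - iz)
}

#' Area-normalized Voigt profile
#'
#' Exact Gaussian (x) Lorentzian convolution evaluated through the Faddeeva
#' function.  `gamma = 0` degenerates to a pure Gaussian and `sigma = 0` to a
#' pure Lorentzian; the profile integrates to `area`.
#'
#' @param x axis values (cm^-1).
#' @param center line center (cm^-1).
#' @param sigma Gaussian standard deviation (cm^-1), `>= 0`.
#' @param gamma Lorentzian half-width at half-maximum (cm^-1), `>= 0`.
#' @param area integrated intensity (intensity * cm^-1).
#' @return Numeric vector of profile values.
#' @examples
#' x <- seq(-10, 10, 0.1)
#' all.equal(voigt_profile(x, 0, 1, 0, 1), dnorm(x))  # Gaussian limit
#' @export
voigt_profile <- function(x, center, sigma, gamma, area = 1) {
  if (sigma < 0 || gamma < 0) stop("widths must be non-negative",
                                   call. = FALSE)
  if (sigma == 0 && gamma == 0)
    stop("sigma and gamma cannot both be zero", call. = FALSE)
  if (sigma == 0)
    return(area * gamma / (pi * ((x - center)^2 + gamma^2)))
  z <- complex(real = (x - center), imaginary = gamma) / (sigma * sqrt(2))
  area * Re(faddeeva_w(z)) / (sigma * sqrt(2 * pi))
}

# Voigt value plus analytic partials wrt (area, center, sigma, gamma);
# used for fast Levenberg-Marquardt Jacobians.  Requires sigma > 0.
voigt_with_grad <- function(x, center, sigma, gamma, area) {
  s2 <- sigma * sqrt(2)
  z <- complex(real = (x - center), imaginary = gamma) / s2
  w <- faddeeva_w(z)
  wp <- -2 * z * w + 2i / sqrt(pi)       # w'(z)
  norm <- 1 / (sigma * sqrt(2 * pi))
  v1 <- Re(w) * norm                     # unit-area profile
  val <- area * v1
  d_center <- area * norm * Re(wp * (-1 / s2))
  d_gamma  <- area * norm * Re(wp * (1i / s2))
  d_sigma  <- -val / sigma + area * norm * Re(wp * (-z / sigma))
  list(value = val, d_area = v1, d_center = d_center,
       d_sigma = d_sigma, d_gamma = d_gamma)
}
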