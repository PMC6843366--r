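test_that("Voigt profile reduces to its Gaussian and Lorentzian limits", {
  x <- seq(-25, 25, by = 0.05)
  expect_equal(voigt_profile(x, 0, 1, 0, 1), dnorm(x), tolerance = 1e-12)
  expect_equal(voigt_profile(x, 0, 0, 2, 3),
               3 * dcauchy(x, 0, 2), tolerance = 1e-12)
  # mixed case against direct numerical convolution
  v <- voigt_profile(x, 1, 1.3, 0.7, 2)
  conv <- vapply(x, function(xx)
    2 * stats::integrate(function(t) dnorm(t, 1, 1.3) * dcauchy(xx - t, 0, 0.7),
                         -Inf, Inf, rel.tol = 1e-10)$value, 1)
  expect_equal(v, conv, tolerance = 1e-9)
  expect_error(voigt_profile(x, 0, 0, 0, 1), "zero")
})

test_that("second-derivative minima find Gaussian centers and the six-band scheme", {
  ax <- seq(3000, 3800, by = 4)
  g <- spectrum_trace(ax, dnorm(ax, 3400, 40))
  m <- second_derivative_minima(g)
  expect_length(m, 1)
  expect_lt(abs(m - 3400), 4 + 1e-9)       # within one grid step
  env <- make_envelope(c(1.4, 1.7, 1.1, 0.9, 0.8, 0.7))
  m6 <- second_derivative_minima(env)
  expect_length(m6, 6)
  expect_true(all(abs(m6 - sort(oh_centers)) <= 10))
  flat <- spectrum_trace(ax, rep(1, length(ax)))
  expect_length(second_derivative_minima(flat), 0)
  expect_error(second_derivative_minima(g, smooth_window = 10000), "window")
})

test_that("noiseless six-Voigt round trip recovers every percent area within 1%", {
  set.seed(42)
  for (rep in 1:8) {
    centers <- oh_centers + runif(6, -15, 15)
    areas <- runif(6, 0.5, 2)
    env <- make_envelope(areas, centers = centers)
    dc <- fit_bands(env, init_centers = centers + runif(6, -10, 10),
                    sigma_range = c(5, 45), gamma_range = c(0, 18))
    expect_gte(dc$r_squared, 0.99999)
    truth <- 100 * areas[order(-centers)] / sum(areas)
    expect_true(all(abs(dc$percent_areas - truth) < 1),
                label = sprintf("replicate %d", rep))
  }
})

test_that("noisy envelope still fits in the R^2 ~ 0.9999 regime", {
  env <- make_envelope(c(1.2, 1.5, 1.0, 0.9, 0.8, 0.6))
  set.seed(7)
  peak_h <- max(env$intensity)
  noisy <- spectrum_trace(env$axis,
                          env$intensity + rnorm(length(env$axis),
                                                0, 0.01 * peak_h))
  dc <- deconvolve_oh(noisy)
  expect_gte(dc$r_squared, 0.999)
})

test_that("single-Gaussian trace is recovered exactly with gamma at zero", {
  ax <- seq(3200, 3600, by = 2)
  g <- spectrum_trace(ax, voigt_profile(ax, 3400, 30, 0, 2.5))
  dc <- fit_bands(g, 3390)
  expect_equal(dc$peaks$center, 3400, tolerance = 1e-6)
  expect_equal(dc$peaks$area, 2.5, tolerance = 1e-6)
  expect_lt(dc$peaks$gamma, 1e-4)
})

test_that("percent areas are normalized shares of the fitted areas", {
  env <- make_envelope(rep(1, 6))
  dc <- fit_bands(env, oh_centers)
  expect_equal(sum(dc$percent_areas), 100, tolerance = 1e-6)
  expect_equal(percent_areas(dc), dc$percent_areas)
  dc2 <- dc
  dc2$peaks$area <- c(1, 1, 1, 1, 1, 5)
  expect_equal(percent_areas(dc2)[6], 50)
  dc2$peaks$area <- rep(0, 6)
  expect_error(percent_areas(dc2), "zero")
})

test_that("deconvolution is scale-equivariant", {
  env <- make_envelope(c(1.1, 1.6, 0.9, 1.0, 0.7, 0.5))
  dc1 <- fit_bands(env, oh_centers)
  dc2 <- fit_bands(spectrum_trace(env$axis, 3 * env$intensity), oh_centers)
  expect_equal(dc2$peaks$area, 3 * dc1$peaks$area, tolerance = 1e-6)
  expect_equal(dc2$percent_areas, dc1$percent_areas, tolerance = 1e-6)
  expect_equal(dc2$r_squared, dc1$r_squared, tolerance = 1e-9)
})

test_that("C-H overlap subtraction removes the doublet and only the doublet", {
  ax <- seq(2600, 3800, by = 4)
  oh <- voigt_profile(ax, 3360, 60, 10, 3) + voigt_profile(ax, 3200, 55, 10, 2)
  ch <- voigt_profile(ax, 2922, 18, 6, 0.8) + voigt_profile(ax, 2848, 16, 5, 0.5)
  s <- spectrum_trace(ax, oh + ch)
  out <- subtract_overlap(s)
  win <- out$axis >= 3000 & out$axis <= 3800
  resid_contam <- trapz_area(out$axis[win], abs(out$intensity[win] - oh[win]))
  ch_area <- 1.3
  expect_lt(resid_contam, 0.01 * ch_area)
  # pure C-H doublet: near-zero trace after self-subtraction
  s_ch <- spectrum_trace(ax, ch)
  out_ch <- subtract_overlap(s_ch)
  expect_lt(max(out_ch$intensity), 0.02 * max(ch))
  # zero intensity in the window: identity with a notice
  s_oh <- spectrum_trace(ax, voigt_profile(ax, 3400, 50, 5, 1))
  expect_message(out_id <- subtract_overlap(s_oh), "unchanged")
  expect_equal(out_id$intensity, s_oh$intensity)
})
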