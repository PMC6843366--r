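make_deconv_with_areas <- function(areas) {
  env <- make_envelope(areas)
  dc <- fit_bands(env, oh_centers, sigma_range = c(5, 45),
                  gamma_range = c(0, 18))
  dc
}

test_that("population ratio groups the two high-wavenumber bands over the rest", {
  dc <- make_deconv_with_areas(rep(1, 6))
  expect_equal(population_ratio(dc), 0.5, tolerance = 1e-3)
  dc2 <- make_deconv_with_areas(c(30, 20, 20, 15, 10, 5))
  expect_equal(population_ratio(dc2), 1.0, tolerance = 1e-3)
  dc5 <- dc
  dc5$peaks <- dc$peaks[1:5, ]
  expect_error(population_ratio(dc5), "six")
})

test_that("van 't Hoff fit recovers an exactly constructed enthalpy", {
  R_gas <- 8.31446
  temps <- c(250, 265, 280, 295, 310, 325, 340)
  dh <- 10596; ds <- 35.9
  ratios <- exp(-dh / (R_gas * temps) + ds / R_gas)
  vh <- vant_hoff_fit(temps, ratios)
  expect_equal(vh$delta_h, dh, tolerance = 1e-9)
  expect_equal(vh$delta_s, ds, tolerance = 1e-9)
  expect_equal(vh$fit_r_squared, 1, tolerance = 1e-12)
  # flat ratios: zero enthalpy
  expect_equal(vant_hoff_fit(temps, rep(0.7, 7))$delta_h, 0)
  expect_error(vant_hoff_fit(temps[1:2], ratios[1:2]), "3")
  expect_error(vant_hoff_fit(temps, -ratios), "positive")
})

test_that("scaling every ratio shifts only the entropy", {
  temps <- seq(250, 340, length.out = 8)
  ratios <- exp(-1200 / temps + 4)
  a <- vant_hoff_fit(temps, ratios)
  b <- vant_hoff_fit(temps, 3 * ratios)
  expect_equal(a$delta_h, b$delta_h, tolerance = 1e-9)
  expect_equal(b$delta_s - a$delta_s, 8.31446 * log(3), tolerance = 1e-9)
})

test_that("enthalpy estimator is nearly unbiased at 2% ratio noise", {
  R_gas <- 8.31446
  temps <- seq(250, 340, length.out = 10)
  dh <- 10596
  truth <- exp(-dh / (R_gas * temps) + 35.9 / R_gas)
  set.seed(123)
  est <- replicate(200, {
    vant_hoff_fit(temps, truth * (1 + rnorm(10, 0, 0.02)))$delta_h
  })
  expect_lt(abs(mean(est) / dh - 1), 0.005)
})

test_that("isosbestic point of a constructed two-state series is recovered", {
  ser <- gen_oh_series(noise = 0, seed = 1)
  basis <- attr(ser, "basis")
  dx <- diff(ser$axis)[1]
  diff_b <- basis[[1]] - basis[[2]]
  cross <- ser$axis[which(diff(sign(diff_b)) != 0)]
  iso <- find_isosbestic(ser)
  expect_true(iso$present)
  expect_lt(min(abs(iso$center - cross)), dx + 1e-9)
  # identical spectra: degenerate, no isosbestic reported
  sp <- replicate(4, ser$spectra[[1]], simplify = FALSE)
  ser_id <- spectral_series(sp, 1:4)
  iso_id <- find_isosbestic(ser_id)
  expect_true(iso_id$degenerate)
  expect_false(iso_id$present)
  # independent random spectra: absent
  set.seed(5)
  sp_r <- lapply(1:5, function(i)
    spectrum_trace(ser$axis, runif(length(ser$axis), 0.5, 1.5)))
  expect_false(find_isosbestic(spectral_series(sp_r, 1:5))$present)
})

test_that("full pipeline: deconvolution ratios follow the generating law", {
  ser <- gen_oh_series(noise = 0, seed = 3)
  truth <- attr(ser, "true_ratio")
  R_hat <- vapply(ser$spectra, function(sp) population_ratio(deconvolve_oh(sp)), 1)
  expect_true(all(abs(R_hat / truth - 1) < 0.01))
  vh <- vant_hoff_fit(ser$condition, R_hat)
  expect_equal(vh$delta_h, 10596, tolerance = 0.01)
  expect_gte(vh$fit_r_squared, 0.99)
})
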