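test_that("generators are deterministic in the seed", {
  a <- gen_phase_solubility(seed = 11)
  b <- gen_phase_solubility(seed = 11)
  expect_identical(a$solubility, b$solubility)
  expect_false(identical(gen_phase_solubility(seed = 12)$solubility,
                         a$solubility))
  t1 <- gen_titration(seed = 4)
  t2 <- gen_titration(seed = 4)
  expect_identical(t1$absorbance, t2$absorbance)
  s1 <- gen_oh_series(seed = 9, noise = 0.01)
  s2 <- gen_oh_series(seed = 9, noise = 0.01)
  expect_identical(s1$spectra[[3]]$intensity, s2$spectra[[3]]$intensity)
  d1 <- gen_diffusion(noise = 0.02, seed = 2)
  d2 <- gen_diffusion(noise = 0.02, seed = 2)
  expect_identical(d1$d_obs_guest, d2$d_obs_guest)
})

test_that("noiseless phase-solubility output is the exact closed-form line", {
  d <- gen_phase_solubility(kc = 6031, s0 = 2e-5, cv = 0)
  slope <- 6031 * 2e-5 / (1 + 6031 * 2e-5)
  expect_equal(round(slope, 4), 0.1076)
  expect_equal(d$solubility, 2e-5 + slope * d$cd_conc, tolerance = 1e-12)
  expect_equal(d$cd_conc, seq(0, 9e-3, 1e-3))
})

test_that("titration generator respects speciation and the printed host grid", {
  td <- gen_titration(noise_sd = 0)
  expect_equal(td$h_tot[-1],
               c(4.43e-5, 8.86e-5, 1.33e-4, 2.21e-4, 4.43e-4, 6.64e-4,
                 2.21e-3))
  # at the largest host excess, >= 89% of the guest is bound (Kc = 6025)
  st <- solve_speciation(binding_model(1, 1, log10(6025)), 2.21e-3, 4.43e-5)
  f <- 1 - st$free_g / 4.43e-5
  expect_gte(f, 0.89)
  # the last-row spectrum is dominated by the complex absorptivity
  E <- attr(td, "true_epsilon")
  recon <- st$free_g * E[1, ] + (4.43e-5 - st$free_g) * E[2, ]
  expect_equal(td$absorbance[8, ], recon, tolerance = 1e-6,
               ignore_attr = TRUE)
  # no complexes: every row proportional to the free-guest shape
  td0 <- gen_titration(model = binding_model(1, 1, -20), noise_sd = 0,
                       epsilon_specs = default_epsilon_specs())
  ratio <- td0$absorbance[5, ] / td0$absorbance[1, ]
  expect_equal(ratio[is.finite(ratio)],
               rep(1, sum(is.finite(ratio))), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("O-H series conserves total area and matches its van 't Hoff law", {
  ser <- gen_oh_series(noise = 0, seed = 1)
  areas <- vapply(ser$spectra, function(s) trapz_area(s$axis, s$intensity), 1)
  # total generated area is 1 up to tail truncation at the window edges
  expect_true(all(abs(areas - mean(areas)) < 0.01 * mean(areas)))
  truth <- attr(ser, "true_ratio")
  R_gas <- 8.31446
  lnR <- -10596 / (R_gas * ser$condition) + 35.9 / R_gas
  expect_equal(log(truth), lnR, tolerance = 1e-12)
})

test_that("noiseless diffusion output inverts back to the generating Kc", {
  m <- gen_diffusion(kc = 6025, noise = 0)
  f <- bound_fraction(m)
  expect_equal(as.numeric(f), attr(m, "true_f"), tolerance = 1e-12)
  kc_hat <- kc_from_diffusion(f, m$h_tot, m$g_tot)
  expect_equal(kc_hat, 6025, tolerance = 1e-9)
  # saturation limits
  m_lo <- gen_diffusion(kc = 1e-6, noise = 0)
  expect_equal(m_lo$d_obs_guest, m_lo$d_free_guest, tolerance = 1e-6)
  m_hi <- gen_diffusion(kc = 1e9, h_tot = 1, g_tot = 1e-5, noise = 0)
  expect_equal(m_hi$d_obs_guest, m_hi$d_complex, tolerance = 1e-6)
})
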