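test_that("speciation matches the 1:1 quadratic closed form across regimes", {
  for (K in 10^c(0, 2, 4, 6, 8)) {
    m <- binding_model(1, 1, log10(K))
    for (tot in 10^seq(-7, -2, by = 1)) {
      st <- solve_speciation(m, tot, tot)
      hg <- complex_1to1(K, tot, tot)
      expect_equal(unname(st$conc["H1G1"]), hg, tolerance = 1e-9,
                   label = sprintf("K=%g tot=%g", K, tot))
    }
  }
  # the worked 1:1 example: K = 6025, equimolar 4.43e-5 M
  st <- solve_speciation(binding_model(1, 1, log10(6025)), 4.43e-5, 4.43e-5)
  expect_equal(unname(st$conc["H1G1"]), 7.96e-6, tolerance = 1e-3)
})

test_that("speciation mass balance holds to 1e-10 relative, richer models too", {
  models <- list(binding_model(1, 1, 3.8),
                 binding_model(c(1, 1), c(1, 2), c(3.8, 6.5)),
                 binding_model(c(1, 2), c(1, 1), c(3.8, 6.2)))
  for (m in models) for (ht in c(1e-5, 4.43e-4, 2.21e-3)) {
    st <- solve_speciation(m, ht, 4.43e-5)
    sp <- m$species
    expect_equal(sum(sp$h * st$conc), ht, tolerance = 1e-10)
    expect_equal(sum(sp$g * st$conc), 4.43e-5, tolerance = 1e-10)
    expect_true(all(st$conc >= 0))
  }
})

test_that("degenerate totals are exact boundary cases", {
  m <- binding_model(1, 1, 5)
  st0 <- solve_speciation(m, 0, 1e-4)
  expect_equal(st0$free_g, 1e-4)
  expect_equal(unname(st0$conc["H1G1"]), 0)
  # vanishing constants: free concentrations equal the totals
  st <- solve_speciation(binding_model(1, 1, -30), 1e-3, 1e-4)
  expect_equal(st$free_h, 1e-3, tolerance = 1e-10)
  expect_equal(st$free_g, 1e-4, tolerance = 1e-10)
})

test_that("1:1 bound fraction is monotone in host total and in K", {
  g_tot <- 4.43e-5
  h_grid <- c(1e-5, 1e-4, 1e-3, 1e-2)
  for (K in c(1e2, 6025)) {
    m <- binding_model(1, 1, log10(K))
    f <- vapply(h_grid, function(ht)
      1 - solve_speciation(m, ht, g_tot)$free_g / g_tot, 1)
    expect_true(all(diff(f) > 0))
  }
  f_k <- vapply(c(10, 1e3, 1e5), function(K)
    1 - solve_speciation(binding_model(1, 1, log10(K)),
                         1e-4, g_tot)$free_g / g_tot, 1)
  expect_true(all(diff(f_k) > 0))
})

test_that("predict_absorbance equals brute-force per-cell summation", {
  m <- binding_model(c(1, 1), c(1, 2), c(3.5, 5.5))
  d <- titration_data(4.43e-5, c(0, 1e-4, 1e-3), seq(250, 300, 10),
                      matrix(0, 3, 6), path_length = 0.8)
  E <- matrix(runif(18, 0, 2e4), 3, 6)    # rows: G, H1G1, H1G2
  A <- predict_absorbance(m, E, d)
  abs_idx <- which(m$species$absorbing)
  for (i in 1:3) {
    st <- solve_speciation(m, d$h_tot[i], d$g_tot)
    for (j in 1:6) {
      a <- 0.8 * sum(st$conc[abs_idx] * E[, j])
      expect_equal(A[i, j], a, tolerance = 1e-12)
    }
  }
  expect_equal(predict_absorbance(m, matrix(0, 3, 6), d),
               matrix(0, 3, 6), ignore_attr = TRUE)
})

test_that("noiseless 1:1 titration is recovered essentially exactly", {
  td <- gen_titration(noise_sd = 0, seed = 1)
  ft <- fit_titration(td, binding_model(1, 1, 3), seed = 2)
  expect_equal(ft$log_beta, log10(6025), tolerance = 1e-3 / log10(6025))
  expect_lt(abs(ft$log_beta - log10(6025)), 1e-3)
  expect_lt(ft$rss, 1e-12 * sum(td$absorbance^2))
  # absorptivity spectra recovered where the species span the points
  expect_equal(ft$epsilon, attr(td, "true_epsilon"), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_false(ft$degenerate)
})

test_that("zero absorbance everywhere flags a degenerate fit", {
  td <- titration_data(4.43e-5, c(0, 1e-4, 2e-4, 4e-4, 1e-3),
                       seq(200, 400, 50), matrix(0, 5, 5))
  ft <- fit_titration(td, binding_model(1, 1, 3))
  expect_true(ft$degenerate)
})

test_that("runs-test verdicts: alternating passes, block signs fail", {
  # alternating signs at every wavelength: no systematic trend
  R_alt <- matrix(rep(c(1, -1), length.out = 7 * 20) * 0.01, 7, 20)
  v <- residual_trend_test(R_alt)
  expect_false(v$systematic)
  # all-positive-then-all-negative at every wavelength: runs = 2
  R_blk <- matrix(rep(c(1, 1, 1, 1, -1, -1, -1) * 0.01, 20), 7, 20)
  v2 <- residual_trend_test(R_blk)
  expect_true(v2$systematic)
  expect_true(all(v2$p_values < 0.05))
  # zeros count as positive signs
  R0 <- R_blk; R0[1, ] <- 0
  expect_true(residual_trend_test(R0)$systematic)
})

test_that("a wrong 1:2-only model fits far worse than the true 1:1 model", {
  # sign-runs statistics have little power against the wavy residual
  # pattern this misfit leaves on 8 points, but the lack of fit itself
  # is gross and AICc ranks the wrong stoichiometry last
  res <- vapply(1:5, function(s) {
    td <- gen_titration(noise_sd = 0.002, seed = s)
    f11 <- fit_titration(td, binding_model(1, 1, 3), seed = s, starts = 5)
    f12 <- fit_titration(td, binding_model(1, 2, 4), seed = s, starts = 5)
    c(f12$rss / f11$rss, f12$aicc > f11$aicc)
  }, numeric(2))
  expect_true(all(res[1, ] > 2))
  expect_true(all(res[2, ] == 1))
})

test_that("single-candidate selection is trivial; 1:1 wins on 1:1 data", {
  td <- gen_titration(noise_sd = 0.002, seed = 11)
  sole <- select_model(td, list(binding_model(1, 1, 3)), seed = 1)
  expect_equal(sole$best, 1L)
  sel <- select_model(td, cand_models(), seed = 3)
  expect_equal(sel$table$model[sel$best], "1:1")
  expect_false(sel$table$systematic_trend[1])
})

test_that("1:1+1:2 data expose the 1:1-only model by its residual trend", {
  m_gen <- binding_model(c(1, 1), c(1, 2), c(log10(6025), 8.2))
  specs <- c(default_epsilon_specs(),
             list(data.frame(center = 300, width = 30, height = 22000)))
  td <- gen_titration(model = m_gen, epsilon_specs = specs,
                      noise_sd = 0.002, seed = 5)
  ft <- fit_titration(td, binding_model(1, 1, 3), seed = 5)
  expect_true(ft$trend$systematic)
})
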