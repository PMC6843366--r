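# shared fixture builders; everything is generated in code at test time

oh_centers <- c(3525, 3439, 3360, 3277, 3191, 3084)

# six-Voigt envelope with known areas on the canonical O-H grid
make_envelope <- function(areas, centers = oh_centers, sigma = 28,
                          gamma = 8, axis = seq(3000, 3800, by = 4)) {
  y <- numeric(length(axis))
  for (i in seq_along(centers))
    y <- y + voigt_profile(axis, centers[i], sigma, gamma, areas[i])
  spectrum_trace(axis, y)
}

# closed-form 1:1 complex concentration: small root of
# x^2 - (ht+gt+1/K)x + ht*gt, in the cancellation-free form
complex_1to1 <- function(K, h_tot, g_tot) {
  b <- h_tot + g_tot + 1 / K
  2 * h_tot * g_tot / (b + sqrt(b^2 - 4 * h_tot * g_tot))
}

cand_models <- function() {
  list(binding_model(1, 1, 3),
       binding_model(c(1, 1), c(1, 2), c(3, 5)),
       binding_model(c(1, 2), c(1, 1), c(3, 5)))
}
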