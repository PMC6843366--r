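test_that("CSV spectra parse, with and without header, and reject garbage", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("3000,0.1", "3001,0.2"), f)
  s <- read_spectrum(f, "csv")
  expect_s3_class(s, "cd_spectrum")
  expect_equal(s$axis, c(3000, 3001))
  expect_equal(s$intensity, c(0.1, 0.2))

  writeLines(c("axis,intensity", "3001,0.2", "3000,0.1"), f)
  s2 <- read_spectrum(f, "csv")
  expect_equal(s2$axis, c(3000, 3001))   # re-ordered ascending
  expect_equal(s2$intensity, c(0.1, 0.2))

  writeLines(character(), f)
  expect_error(read_spectrum(f, "csv"), "empty")
  writeLines(c("3000,0.1", "3000,0.2"), f)
  expect_error(read_spectrum(f, "csv"), "monotone")
  writeLines(c("3000,0.1", "3001,abc"), f)
  expect_error(read_spectrum(f, "csv"), "line 2")
  expect_error(read_spectrum(file.path(tempdir(), "nope.csv"), "csv"),
               "not found")
})

test_that("write/read round trip preserves values and metadata in both dialects", {
  ax <- seq(3000, 3800, by = 7.5)
  s <- spectrum_trace(ax, exp(sin(seq(0, 6, length.out = length(ax)))) - 0.5,
                      modality = "FTIR-ATR", temperature = 290)
  for (fmt in c("csv", "jcamp-dx")) {
    f <- withr::local_tempfile(fileext = if (fmt == "csv") ".csv" else ".jdx")
    write_spectrum(s, f, fmt)
    r <- read_spectrum(f, fmt)
    expect_equal(r$axis, s$axis, tolerance = 1e-6)
    expect_equal(r$intensity, s$intensity, tolerance = 1e-6)
    expect_identical(r$modality, s$modality)
    expect_equal(r$temperature, 290)
  }
})

test_that("JCAMP-DX XYDATA (X++(Y..Y)) form with factors is accepted", {
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=fixture", "##JCAMP-DX=4.24",
               "##XFACTOR=2", "##YFACTOR=0.5",
               "##FIRSTX=2000", "##LASTX=2006", "##NPOINTS=4",
               "##XYDATA=(X++(Y..Y))",
               "1000 2 4 6", "1003 8",
               "##END="), f)
  s <- read_spectrum(f, "jcamp-dx")
  expect_equal(s$axis, c(2000, 2002, 2004, 2006))
  expect_equal(s$intensity, c(1, 2, 3, 4))
})

test_that("crop keeps original intensities in-window and validates bounds", {
  s <- spectrum_trace(seq(400, 4000, by = 4), sqrt(seq(400, 4000, by = 4)))
  c1 <- crop(s, 3800, 3000)                # bounds in spectroscopist order
  expect_true(all(c1$axis >= 3000 & c1$axis <= 3800))
  expect_equal(c1$intensity, sqrt(c1$axis))
  expect_equal(crop(s, 400, 4000)$axis, s$axis)     # full range = identity
  expect_error(crop(s, 5000, 6000), "overlap")
})

test_that("normalization contracts: unit area, idempotence, scale invariance", {
  s <- make_envelope(c(2, 3, 4, 3, 2, 1))
  n <- normalize(s, "unit-area")
  expect_equal(trapz_area(n$axis, n$intensity), 1, tolerance = 1e-9)
  n2 <- normalize(n, "unit-area")
  expect_equal(n2$intensity, n$intensity, tolerance = 1e-12)
  s7 <- spectrum_trace(s$axis, 7 * s$intensity)
  expect_equal(normalize(s7, "unit-area")$intensity, n$intensity,
               tolerance = 1e-12)
  expect_equal(max(normalize(s, "unit-max")$intensity), 1)
  z <- spectrum_trace(1:5, rep(0, 5))
  expect_error(normalize(z), "all-zero")
})

test_that("crop then normalize commutes with normalize-on-window", {
  s <- make_envelope(c(1, 2, 1, 3, 1, 2))
  a <- normalize(crop(s, 3100, 3700), "unit-area")
  b <- normalize(crop(normalize(s, "unit-area"), 3100, 3700), "unit-area")
  expect_equal(a$intensity, b$intensity, tolerance = 1e-9)
})

test_that("spectral series demands a shared grid and sorts by condition", {
  ax <- seq(3000, 3100, 10)
  sp <- lapply(3:1, function(i) spectrum_trace(ax, rep(i, length(ax))))
  ser <- spectral_series(sp, c(300, 280, 260))
  expect_equal(ser$condition, c(260, 280, 300))
  expect_equal(ser$spectra[[1]]$intensity[1], 1)
  bad <- c(sp[1:2], list(spectrum_trace(ax + 1, rep(1, length(ax)))))
  expect_error(spectral_series(bad, 1:3), "identical axis")
  expect_error(spectral_series(sp, c(1, 1, 2)), "unique")
})
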