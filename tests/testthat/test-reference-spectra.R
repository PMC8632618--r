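test_that("extinction-to-absorption conversion applies ln(10) * C / MW in mm^-1", {
  wl <- seq(500, 600, by = 10)
  eps <- spectrum_tbl(wl, rep(1, length(wl)), "extinction_Lmol1cm1")
  out <- convert_extinction_to_absorption(eps, 150, 64500)
  # ln(10) * 150/64500 cm^-1 = 5.3556e-3 cm^-1 = 5.3556e-4 mm^-1
  expect_equal(out$value, rep(log(10) * 150 / 64500 / 10, length(wl)))
  expect_equal(out$value[1], 5.355e-4, tolerance = 1e-3)
  expect_equal(spectrum_unit(out), "absorption_mm1")
  expect_equal(out$wavelength_nm, wl)

  zero <- convert_extinction_to_absorption(
    spectrum_tbl(wl, rep(0, length(wl)), "extinction_Lmol1cm1"), 150, 64500)
  expect_true(all(zero$value == 0))

  doubled <- convert_extinction_to_absorption(eps, 300, 64500)
  expect_equal(doubled$value, 2 * out$value)

  expect_error(convert_extinction_to_absorption(eps, -1, 64500),
               class = "hb_error_parameter")
  expect_error(convert_extinction_to_absorption(eps, 150, 0),
               class = "hb_error_parameter")
})

test_that("conversion round-trips back to extinction", {
  wl <- 490:620
  eps <- spectrum_tbl(wl, 1000 + 50 * sin(wl / 10), "extinction_Lmol1cm1")
  mu <- convert_extinction_to_absorption(eps, 150, 64500)
  back <- mu$value * 10 / (log(10) * 150 / 64500)
  expect_equal(back, eps$value, tolerance = 1e-12)
})

test_that("resampling is exact on lines, idempotent, and refuses extrapolation", {
  spec <- spectrum_tbl(seq(480, 640, by = 2), 0.5 * seq(480, 640, by = 2) - 3,
                       "absorption_mm1")
  grid <- analysis_grid(490, 620, 37)
  out <- resample_spectrum(spec, grid)
  expect_equal(out$value, 0.5 * grid_wavelengths(grid) - 3)
  expect_equal(spectrum_unit(out), "absorption_mm1")

  # own grid -> identity
  wl <- grid_wavelengths(grid)
  own <- spectrum_tbl(wl, sin(wl / 7), "dimensionless")
  expect_equal(resample_spectrum(own, grid)$value, own$value)

  # constant stays constant
  const <- spectrum_tbl(seq(480, 640, by = 2), rep(4, 81))
  expect_true(all(resample_spectrum(const, grid)$value == 4))

  # monotone input stays monotone under linear interpolation
  mono <- spectrum_tbl(seq(480, 640, by = 2), cumsum(runif(81)))
  expect_true(all(diff(resample_spectrum(mono, grid)$value) >= 0))

  expect_error(resample_spectrum(spec, analysis_grid(400, 620, 10)),
               class = "hb_error_range")
})

test_that("band normalization divides by the closed-band mean", {
  s <- spectrum_tbl(c(525, 555, 585), c(1, 2, 3))
  out <- normalize_band(s, 525, 585)
  expect_equal(out$value, c(0.5, 1.0, 1.5))

  wl <- seq(490, 620, length.out = 80)
  s2 <- spectrum_tbl(wl, 2 + sin(wl / 9))
  n1 <- normalize_band(s2)
  idx <- wl >= 525 & wl <= 585
  expect_equal(mean(n1$value[idx]), 1)
  # idempotent
  expect_equal(normalize_band(n1)$value, n1$value)
  # constant -> all ones
  expect_true(all(normalize_band(spectrum_tbl(wl, rep(7, 80)))$value == 1))

  zero <- spectrum_tbl(wl, c(rep(0, 70), rep(1, 10)))
  expect_error(normalize_band(zero, 490, 520),
               class = "hb_error_degenerate")
})

test_that("residual normalization uses the band mean of mu_t, not of the residual", {
  wl <- seq(490, 620, length.out = 50)
  mu_t <- spectrum_tbl(wl, rep(4, 50), "attenuation_mm1")
  res <- spectrum_tbl(wl, rep(1, 50), "attenuation_mm1")
  out <- normalize_residual(res, mu_t)
  expect_equal(out$value, rep(0.25, 50))

  # residual = mu_t reduces to plain band normalization of mu_t
  expect_equal(normalize_residual(mu_t, mu_t)$value,
               normalize_band(mu_t)$value)
  # zero residual stays zero
  zero <- spectrum_tbl(wl, rep(0, 50))
  expect_true(all(normalize_residual(zero, mu_t)$value == 0))

  other <- spectrum_tbl(wl + 1, rep(1, 50))
  expect_error(normalize_residual(other, mu_t), class = "hb_error_grid")
})

test_that("spectrum files round-trip with the unit in the header", {
  wl <- seq(500, 600, by = 5)
  spec <- spectrum_tbl(wl, runif(length(wl)), "absorption_mm1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(spec, path)
  back <- read_spectrum(path)
  expect_equal(back$value, spec$value)
  expect_equal(spectrum_unit(back), "absorption_mm1")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("wavelength_nm\tfurlongs", "500\t1", "510\t2"), bad)
  expect_error(read_spectrum(bad), class = "hb_error_unit")
})

test_that("spectrum invariants are enforced", {
  expect_error(spectrum_tbl(c(500, 500, 510), 1:3),
               class = "hb_error_spectrum")
  expect_error(spectrum_tbl(c(510, 500), 1:2), class = "hb_error_spectrum")
  expect_error(spectrum_tbl(500, 1), class = "hb_error_spectrum")
  expect_error(spectrum_tbl(c(500, 510), c(1, NA)),
               class = "hb_error_spectrum")
  expect_error(analysis_grid(620, 490), class = "hb_error_parameter")
  expect_error(analysis_grid(490, 620, 1), class = "hb_error_parameter")
})

test_that("a basis config with extinction inputs loads converted and aligned", {
  dir <- withr::local_tempdir()
  wl <- seq(485, 625, by = 1)
  shapes <- list(
    Hb = 30000 * exp(-((wl - 556)^2) / 500) + 1000,
    HbO2 = 50000 * exp(-((wl - 542)^2) / 300) + 800,
    metHb = 20000 * exp(-((wl - 500)^2) / 900) + 2000
  )
  for (nm in names(shapes)) {
    write_spectrum(spectrum_tbl(wl, shapes[[nm]], "extinction_Lmol1cm1"),
                   file.path(dir, paste0(nm, ".tsv")))
  }
  cfg <- list(name = "tabulated", concentration_g_per_L = 150,
              molecular_weight_g_per_mol = 64500,
              components = list(Hb = "Hb.tsv", HbO2 = "HbO2.tsv",
                                metHb = "metHb.tsv"))
  basis <- read_basis_config(cfg, dir = dir)
  expect_s3_class(basis, "chromophore_basis")
  expect_equal(basis_name(basis), "tabulated")
  expect_equal(basis$Hb,
               convert_extinction_to_absorption(
                 spectrum_tbl(wl, shapes$Hb, "extinction_Lmol1cm1"),
                 150, 64500)$value)

  cfg$components$metHb <- "missing.tsv"
  expect_error(read_basis_config(cfg, dir = dir), class = "hb_error_config")
})

test_that("basis constructor enforces shared grid and non-negativity", {
  wl <- seq(490, 620, length.out = 20)
  a <- spectrum_tbl(wl, runif(20), "absorption_mm1")
  b <- spectrum_tbl(wl + 1, runif(20), "absorption_mm1")
  expect_error(chromophore_basis("x", a, b, a), class = "hb_error_grid")
  neg <- spectrum_tbl(wl, runif(20) - 2, "absorption_mm1")
  expect_error(chromophore_basis("x", a, a, neg), class = "hb_error_basis")
})
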