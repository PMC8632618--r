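test_that("noiseless two-component attenuation is recovered to 1e-6", {
  grid <- tiny_grid()
  basis <- tiny_basis(grid)
  mu_t <- spectrum_tbl(basis$wavelength_nm,
                       0.9 * basis$HbO2 + 0.1 * basis$Hb,
                       "attenuation_mm1")
  fit <- fit_attenuation(mu_t, basis, grid)
  expect_lt(max(abs(fit$fractions - c(0.1, 0.9, 0))), 1e-6)
  expect_lt(fit$alpha, 1e-6)
  expect_equal(fit$so2, 90, tolerance = 1e-6)
})

test_that("pure oxyhemoglobin input gives SO2 = 100", {
  grid <- tiny_grid()
  basis <- tiny_basis(grid)
  mu_t <- spectrum_tbl(basis$wavelength_nm, basis$HbO2, "attenuation_mm1")
  fit <- fit_attenuation(mu_t, basis, grid)
  expect_equal(fit$so2, 100, tolerance = 1e-8)
  expect_equal(compute_so2(fit), 100, tolerance = 1e-8)
})

test_that("fit with scattering and noise recovers parameters to stated accuracy", {
  grid <- analysis_grid()
  basis <- make_synthetic_basis(grid)
  truth_f <- c(0.13, 0.8, 0.07)  # 7% metHb share of total hemoglobin
  est <- sapply(1:50, function(s) {
    truth <- phantom_truth(truth_f[1], truth_f[2], truth_f[3],
                           alpha = 0.5, beta = 1.3, basis = basis)
    # 1% multiplicative noise directly on mu_t
    set.seed(s)
    noisy <- forward_mu_t(truth)
    noisy$value <- noisy$value * exp(rnorm(nrow(noisy), 0, 0.01))
    fit <- fit_attenuation(spectrum_tbl(noisy$wavelength_nm, noisy$value,
                                        "attenuation_mm1"), basis, grid)
    c(unname(fit$fractions), fit$beta)
  })
  m <- rowMeans(est)
  expect_lt(max(abs(m[1:3] - truth_f) / truth_f), 0.05)
  expect_lt(abs(m[4] - 1.3), 0.1)
})

test_that("reconstruction plus residual conserves the input spectrum", {
  grid <- tiny_grid()
  basis <- tiny_basis(grid)
  for (s in 1:5) {
    truth <- phantom_truth(runif(1, 0, 0.5), runif(1, 0.3, 1),
                           runif(1, 0, 0.1), alpha = runif(1, 0, 1),
                           beta = runif(1, 0.2, 3), basis = basis,
                           noise_sigma = 0.01, seed = s)
    mu_t <- attenuation_spectrum(
      estimate_attenuation(forward_transmission(truth)))
    fit <- fit_attenuation(mu_t, basis, grid)
    recon <- fit$reconstruction$value + fit$residual$value
    expect_equal(recon, fit$mu_t$value, tolerance = 1e-10)
  }
})

test_that("fitting k*mu_t scales amplitudes by k and leaves beta and SO2 alone", {
  grid <- tiny_grid()
  basis <- tiny_basis(grid)
  truth <- phantom_truth(0.2, 0.7, 0.05, alpha = 0.4, beta = 1.7,
                         basis = basis)
  mu_t <- forward_mu_t(truth)
  f1 <- fit_attenuation(mu_t, basis, grid)
  mu_k <- spectrum_tbl(mu_t$wavelength_nm, 2.5 * mu_t$value,
                       "attenuation_mm1")
  f2 <- fit_attenuation(mu_k, basis, grid)
  expect_equal(f2$fractions, 2.5 * f1$fractions, tolerance = 1e-5)
  expect_equal(f2$alpha, 2.5 * f1$alpha, tolerance = 1e-5)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-4)
  expect_equal(f2$so2, f1$so2, tolerance = 1e-6)
})

test_that("absorption-only fit recovers mixtures and is normalization-invariant", {
  grid <- tiny_grid()
  basis <- tiny_basis(grid)
  mu_a <- spectrum_tbl(basis$wavelength_nm,
                       0.5 * basis$Hb + 0.5 * basis$HbO2,
                       "absorption_mm1")
  fit <- fit_absorption(mu_a, basis, grid)
  expect_equal(unname(fit$fractions), c(0.5, 0.5, 0), tolerance = 1e-8)
  expect_equal(fit$so2, 50, tolerance = 1e-8)
  expect_equal(fit$alpha, 0)

  # oracle: unconstrained least squares agrees at an interior optimum
  A <- cbind(basis$Hb, basis$HbO2, basis$metHb)
  ls <- qr.solve(A, mu_a$value)
  expect_equal(unname(fit$fractions), ls, tolerance = 1e-8)

  norm_fit <- fit_absorption(normalize_band(mu_a), basis, grid)
  expect_equal(norm_fit$so2, fit$so2, tolerance = 1e-8)

  pure_met <- spectrum_tbl(basis$wavelength_nm, basis$metHb,
                           "absorption_mm1")
  met_fit <- fit_absorption(pure_met, basis, grid)
  expect_gt(methb_fraction(met_fit), 0.999)
  expect_error(compute_so2(met_fit), class = "hb_error_degenerate")
})

test_that("corrected hemoglobin absorption removes metHb and scattering exactly", {
  grid <- tiny_grid()
  basis <- tiny_basis(grid)
  truth <- phantom_truth(0.25, 0.65, 0.08, alpha = 0.6, beta = 2.1,
                         basis = basis)
  mu_t <- forward_mu_t(truth)
  fit <- fit_attenuation(mu_t, basis, grid)
  corr <- corrected_hemoglobin_absorption(mu_t, fit)
  expected <- 0.25 * basis$Hb + 0.65 * basis$HbO2
  expect_equal(corr$value, expected, tolerance = 1e-6)

  # identity when metHb and scattering are absent
  truth0 <- phantom_truth(0.3, 0.7, 0, alpha = 0, beta = 1, basis = basis)
  mu0 <- forward_mu_t(truth0)
  fit0 <- fit_attenuation(mu0, basis, grid)
  corr0 <- corrected_hemoglobin_absorption(mu0, fit0)
  expect_equal(corr0$value, mu0$value, tolerance = 1e-7)

  # corrected minus fitted Hb+HbO2 reconstruction equals the residual
  hb_part <- fit$fractions[["f_Hb"]] * basis$Hb +
    fit$fractions[["f_HbO2"]] * basis$HbO2
  expect_equal(corr$value - hb_part, fit$residual$value, tolerance = 1e-9)
})

test_that("SO2 arithmetic and guards", {
  expect_equal(compute_so2(c(f_Hb = 0, f_HbO2 = 0.8)), 100)
  expect_equal(compute_so2(c(f_Hb = 0.3, f_HbO2 = 0.3)), 50)
  expect_equal(compute_so2(c(f_Hb = 0.5, f_HbO2 = 0)), 0)
  expect_error(compute_so2(c(f_Hb = 0, f_HbO2 = 0)),
               class = "hb_error_degenerate")
})

test_that("composition summaries follow their defining ratios", {
  grid <- tiny_grid()
  basis <- tiny_basis(grid)

  # scattering_fraction: flat mu_s = 1 over flat mu_t = 4 -> 0.25
  wl <- grid_wavelengths(grid)
  fit_like <- structure(list(alpha = 1, beta = 0,
                             fractions = c(f_Hb = 1, f_HbO2 = 1,
                                           f_metHb = 0)),
                        class = "hb_fit")
  flat <- spectrum_tbl(wl, rep(4, length(wl)), "attenuation_mm1")
  expect_equal(scattering_fraction(fit_like, flat), 0.25)

  zero_alpha <- structure(list(alpha = 0, beta = 1), class = "hb_fit")
  expect_equal(scattering_fraction(zero_alpha, flat), 0)

  pure_scatter <- structure(list(alpha = 2, beta = 0.8), class = "hb_fit")
  mu_s_only <- spectrum_tbl(wl, scattering_mu_s(wl, 2, 0.8),
                            "attenuation_mm1")
  expect_equal(scattering_fraction(pure_scatter, mu_s_only), 1,
               tolerance = 1e-12)

  expect_equal(methb_fraction(c(f_Hb = 1, f_HbO2 = 1, f_metHb = 1)), 1 / 3)
  expect_equal(methb_fraction(c(f_Hb = 0.4, f_HbO2 = 0.5, f_metHb = 0.1)),
               0.1)
  expect_equal(methb_fraction(c(f_Hb = 0.5, f_HbO2 = 0.5, f_metHb = 0)), 0)
  expect_error(methb_fraction(c(f_Hb = 0, f_HbO2 = 0, f_metHb = 0)),
               class = "hb_error_degenerate")
})

test_that("a mismatched basis leaves autocorrelated (non-white) residuals", {
  grid <- analysis_grid(n_points = 200)
  basis_a <- make_synthetic_basis(grid, seed = 1)
  basis_b <- perturb_basis(basis_a, amplitude = 0.05, seed = 11)
  lag1 <- function(x) {
    x <- x - mean(x)
    sum(head(x, -1) * tail(x, -1)) / sum(x^2)
  }
  set.seed(123)
  r_match <- r_mis <- numeric(20)
  for (i in 1:20) {
    truth <- phantom_truth(0.15, 0.85, 0.02, alpha = 0.3, beta = 1.2,
                           basis = basis_a, noise_sigma = 0.005,
                           seed = sample.int(1e6, 1))
    mu_t <- attenuation_spectrum(
      estimate_attenuation(forward_transmission(truth)))
    r_match[i] <- lag1(fit_attenuation(mu_t, basis_a, grid)$norm_residual$value)
    r_mis[i] <- lag1(fit_attenuation(mu_t, basis_b, grid)$norm_residual$value)
  }
  # white-noise null: lag-1 autocorrelation ~ N(0, 1/sqrt(n)); the
  # mismatched fits should exceed it decisively, the matched ones not
  null_sd <- 1 / sqrt(200)
  expect_gt(mean(r_mis > 3 * null_sd), 0.9)
  expect_lt(mean(abs(r_match)), 3 * null_sd)
})

test_that("tidy and glance views expose the fitted parameters", {
  grid <- tiny_grid()
  basis <- tiny_basis(grid)
  truth <- phantom_truth(0.2, 0.8, 0.01, alpha = 0.2, beta = 1,
                         basis = basis)
  fit <- fit_attenuation(forward_mu_t(truth), basis, grid)
  td <- tidy(fit)
  expect_equal(td$term, c("f_Hb", "f_HbO2", "f_metHb", "alpha", "beta"))
  expect_equal(td$estimate[1:3], unname(fit$fractions))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$so2, fit$so2)
  expect_true(gl$converged)
})
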