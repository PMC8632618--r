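#' Generate a synthetic chromophore reference basis
#'
#' Builds three reference absorption spectra with the visible-band
#' structure of the hemoglobin species, for ground-truth testing without
#' tabulated compilations:
#' * HbO2: double-peaked alpha/beta band structure (Gaussians near 542 and
#'   577 nm) on a decaying baseline;
#' * Hb: one broad band near 556 nm;
#' * metHb: broad short-wavelength band plus an elevated 600-620 nm tail.
#'
#' Amplitudes are on the whole-blood scale (tens of mm^-1 at the peaks,
#' matching 150 g/L hemoglobin). The `seed` applies a small deterministic
#' jitter to band centers, widths and amplitudes so different seeds give
#' slightly different but structurally identical bases; all values are
#' strictly positive.
#'
#' @param grid An [analysis_grid()] within 490-620 nm.
#' @param seed Integer seed; same seed, same basis.
#' @return A [chromophore_basis()] named `"synthetic"`.
#' @export
make_synthetic_basis <- function(grid = analysis_grid(), seed = 1) {
  wl <- grid_wavelengths(grid)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  j <- function(x, sd) x * (1 + stats::rnorm(1, 0, sd))
  gauss <- function(center, width, amp) {
    amp * exp(-((wl - center)^2) / (2 * width^2))
  }
  hbo2 <- gauss(j(542, 0.002), j(9, 0.05), j(30, 0.05)) +
    gauss(j(577, 0.002), j(8, 0.05), j(27, 0.05)) +
    4 * exp(-(wl - 490) / 60) + 0.2
  hb <- gauss(j(556, 0.002), j(17, 0.05), j(25, 0.05)) +
    3 * exp(-(wl - 490) / 80) + 0.3
  methb <- gauss(j(500, 0.002), j(30, 0.05), j(18, 0.05)) +
    gauss(j(630, 0.002), j(25, 0.05), j(6, 0.05)) + 0.5
  chromophore_basis(
    "synthetic",
    Hb = spectrum_tbl(wl, hb, "absorption_mm1"),
    HbO2 = spectrum_tbl(wl, hbo2, "absorption_mm1"),
    metHb = spectrum_tbl(wl, methb, "absorption_mm1")
  )
}

#' Define a ground-truth phantom
#'
#' Bundles everything needed to forward-model a liquid hemoglobin phantom:
#' chromophore fractions, power-law scattering, the generating basis,
#' incident intensity and multiplicative intensity noise.
#'
#' @param f_Hb,f_HbO2,f_metHb Chromophore fractions (>= 0), in units of the
#'   basis's reference concentration.
#' @param alpha Scattering amplitude at 550 nm (mm^-1, >= 0).
#' @param beta Scattering power.
#' @param basis Generating [chromophore_basis()].
#' @param I0 Incident intensity (counts, > 0).
#' @param noise_sigma Relative multiplicative (lognormal) intensity noise
#'   standard deviation, >= 0; 0.005 emulates a well-exposed spectrometer.
#' @param seed Integer seed driving all noise draws.
#' @return A list of class `phantom_truth`.
#' @export
phantom_truth <- function(f_Hb, f_HbO2, f_metHb = 0, alpha = 0, beta = 1,
                          basis, I0 = 50000, noise_sigma = 0,
                          seed = 1) {
  f <- c(f_Hb = f_Hb, f_HbO2 = f_HbO2, f_metHb = f_metHb)
  if (any(f < 0) || alpha < 0 || I0 <= 0 || noise_sigma < 0) {
    rlang::abort(paste0("Fractions and alpha must be >= 0, I0 > 0, ",
                        "noise_sigma >= 0."), class = "hb_error_parameter")
  }
  structure(list(fractions = f, alpha = alpha, beta = beta, basis = basis,
                 I0 = I0, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(paste0("<phantom_truth> f_Hb=%.3g f_HbO2=%.3g f_metHb=%.3g ",
                     "alpha=%.3g beta=%.3g I0=%g sigma=%g seed=%d\n"),
              x$fractions[["f_Hb"]], x$fractions[["f_HbO2"]],
              x$fractions[["f_metHb"]], x$alpha, x$beta, x$I0,
              x$noise_sigma, x$seed))
  invisible(x)
}

#' Scattering amplitude that yields a target scattering fraction
#'
#' Solves for the power-law amplitude alpha such that the scattering term
#' contributes a fraction `s` of the summed total attenuation over the
#' grid: alpha = s * sum(mu_a) / ((1 - s) * sum((lambda/550)^-beta)).
#'
#' @param s Target scattering fraction of mu_t, in \[0, 1).
#' @param beta Scattering power.
#' @param mu_a Absorption-only spectrum tibble (sum of the chromophore
#'   terms) on the evaluation grid.
#' @return alpha (mm^-1 at 550 nm).
#' @export
alpha_for_scattering_fraction <- function(s, beta, mu_a) {
  stopifnot(s >= 0, s < 1)
  w <- (mu_a$wavelength_nm / 550)^(-beta)
  s * sum(mu_a$value) / ((1 - s) * sum(w))
}

# Absorption-only part of a phantom's attenuation.
phantom_mu_a <- function(truth, grid = NULL) {
  basis <- truth$basis
  if (!is.null(grid)) basis <- resample_basis(basis, grid)
  spectrum_tbl(basis$wavelength_nm,
               as.numeric(basis_matrix(basis) %*% truth$fractions),
               "absorption_mm1")
}

#' Preset phantoms emulating the three hemoglobin preparations
#'
#' Returns ground truths whose composition signatures emulate the three
#' preparations commonly used in liquid hemoglobin phantoms:
#' * `"wb"` (whole-blood-like): intact erythrocytes contribute a small
#'   scattering term, about 7% of the summed attenuation; metHb below 1%.
#' * `"lb"` (lysed-blood-like): no scattering, metHb below 1%.
#' * `"a0"` (freeze-dried, ferrous-stabilized-hemoglobin-like): lower
#'   concentration, about 8% scattering, metHb near 7% of total hemoglobin
#'   when oxygenated and 42% when deoxygenated.
#'
#' Oxygenated presets sit at SO2 = 97% (full oxygenation is never quite
#' reached in practice); deoxygenated presets at SO2 = 1% with a yeast
#' scattering contribution of 30% (wb), 40% (lb) or 25% (a0) of mu_t.
#'
#' @param preset One of `"wb"`, `"lb"`, `"a0"`.
#' @param state `"oxy"` or `"deoxy"`.
#' @param grid Grid on which scattering-fraction targets are calibrated.
#' @param basis Generating basis; defaults to [make_synthetic_basis()] on
#'   `grid` with seed 1.
#' @param noise_sigma,seed Forwarded to [phantom_truth()].
#' @return A `phantom_truth`.
#' @export
phantom_preset <- function(preset = c("wb", "lb", "a0"),
                           state = c("oxy", "deoxy"),
                           grid = analysis_grid(),
                           basis = make_synthetic_basis(grid),
                           noise_sigma = 0.005, seed = 1) {
  preset <- match.arg(preset)
  state <- match.arg(state)
  total <- switch(preset, wb = 1, lb = 1, a0 = 0.2)  # a0: lower concentration
  methb_share <- switch(preset, wb = 0.005, lb = 0.005,
                        a0 = if (state == "oxy") 0.07 else 0.42)
  so2 <- if (state == "oxy") 97 else 1
  f_methb <- total * methb_share / (1 - methb_share)
  f_hbo2 <- total * so2 / 100
  f_hb <- total - f_hbo2
  truth <- phantom_truth(f_Hb = f_hb, f_HbO2 = f_hbo2, f_metHb = f_methb,
                         alpha = 0, beta = 1, basis = basis,
                         noise_sigma = noise_sigma, seed = seed)
  scat <- if (state == "oxy") {
    switch(preset, wb = 0.07, lb = 0, a0 = 0.08)
  } else {
    # yeast dominates scattering once added
    switch(preset, wb = 0.30, lb = 0.40, a0 = 0.25)
  }
  if (scat > 0) {
    truth$alpha <- alpha_for_scattering_fraction(scat, truth$beta,
                                                 phantom_mu_a(truth, grid))
  }
  truth
}

#' Noiseless forward attenuation spectrum of a phantom
#'
#' mu_t = f_Hb mu_a,Hb + f_HbO2 mu_a,HbO2 + f_metHb mu_a,metHb
#'      + alpha (lambda/550)^(-beta), evaluated on the grid.
#'
#' @param truth A [phantom_truth()].
#' @param grid Optional [analysis_grid()]; defaults to the basis's grid.
#' @return Spectrum tibble in `attenuation_mm1` units.
#' @export
forward_mu_t <- function(truth, grid = NULL) {
  mu_a <- phantom_mu_a(truth, grid)
  mu_s <- scattering_mu_s(mu_a$wavelength_nm, truth$alpha, truth$beta)
  spectrum_tbl(mu_a$wavelength_nm, mu_a$value + mu_s, "attenuation_mm1")
}

#' Forward-model a multi-pathlength transmission series
#'
#' I(lambda, d) = I0 exp(-mu_t(lambda) d) eta(lambda, d), with eta
#' lognormal (meanlog 0, sdlog `noise_sigma`), seeded from the truth's
#' seed. With `noise_sigma = 0` the decay is exact Beer-Lambert.
#'
#' @param truth A [phantom_truth()].
#' @param pathlengths_mm Distinct pathlengths (mm), >= 2 of them. The
#'   default is 13 steps of 25 um from 0 to 0.3 mm.
#' @param grid Optional [analysis_grid()].
#' @return A [transmission_series()].
#' @export
forward_transmission <- function(truth,
                                 pathlengths_mm = seq(0, 0.3, by = 0.025),
                                 grid = NULL) {
  if (length(unique(pathlengths_mm)) < 2L) {
    rlang::abort("Need >= 2 distinct pathlengths.",
                 class = "hb_error_parameter")
  }
  mu_t <- forward_mu_t(truth, grid)
  out <- tidyr::expand_grid(pathlength_mm = sort(pathlengths_mm),
                            wavelength_nm = mu_t$wavelength_nm) |>
    dplyr::left_join(
      tibble::tibble(wavelength_nm = mu_t$wavelength_nm, mu_t = mu_t$value),
      by = "wavelength_nm") |>
    dplyr::mutate(intensity = truth$I0 * exp(-.data$mu_t * .data$pathlength_mm)) |>
    dplyr::select(-"mu_t")
  if (truth$noise_sigma > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(truth$seed)
    eta <- stats::rlnorm(nrow(out), meanlog = 0, sdlog = truth$noise_sigma)
    out$intensity <- out$intensity * eta
  }
  transmission_series(out)
}

#' Deplete a phantom's oxygen to a target saturation
#'
#' Emulates yeast-driven deoxygenation: oxyhemoglobin is converted to
#' deoxyhemoglobin so that SO2 reaches `so2_target`, with the total
#' f_Hb + f_HbO2 conserved exactly and f_metHb untouched. Optionally the
#' added yeast contributes scattering: the power-law amplitude is re-solved
#' so scattering makes up `yeast_scattering_fraction` of the depleted
#' phantom's summed attenuation (yeast scattering dominates any baseline
#' scattering, so the baseline amplitude is absorbed rather than stacked).
#'
#' @param truth A [phantom_truth()].
#' @param so2_target Target SO2 in percent, in \[0, 100\].
#' @param yeast_scattering_fraction Optional target scattering fraction of
#'   mu_t after depletion, in \[0, 1); `NULL` leaves scattering unchanged.
#' @param yeast_beta Scattering power used when re-solving alpha.
#' @return A new `phantom_truth`.
#' @export
deplete_oxygen <- function(truth, so2_target,
                           yeast_scattering_fraction = NULL,
                           yeast_beta = truth$beta) {
  if (!is.finite(so2_target) || so2_target < 0 || so2_target > 100) {
    rlang::abort("`so2_target` must lie in [0, 100].",
                 class = "hb_error_parameter")
  }
  total <- truth$fractions[["f_Hb"]] + truth$fractions[["f_HbO2"]]
  out <- truth
  out$fractions[["f_HbO2"]] <- total * so2_target / 100
  out$fractions[["f_Hb"]] <- total - out$fractions[["f_HbO2"]]
  if (!is.null(yeast_scattering_fraction)) {
    out$beta <- yeast_beta
    out$alpha <- alpha_for_scattering_fraction(
      yeast_scattering_fraction, yeast_beta, phantom_mu_a(out))
  }
  out
}
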