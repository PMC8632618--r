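#' Power-law scattering spectrum
#'
#' Evaluates mu_s(lambda) = alpha * (lambda / 550 nm)^(-beta): a power law
#' pivoted at 550 nm, so `alpha` is the scattering coefficient at 550 nm
#' (mm^-1) and `beta` its spectral slope. Anisotropy is folded into alpha
#' (mu_s = mu_s' / (1 - g) with g assumed spectrally flat over the band).
#'
#' @param wavelength_nm Wavelengths (nm).
#' @param alpha Scattering amplitude at 550 nm (mm^-1), >= 0.
#' @param beta Scattering power (dimensionless).
#' @param reference_nm Pivot wavelength; 550 by convention.
#' @return Numeric vector of mu_s values (mm^-1).
#' @export
scattering_mu_s <- function(wavelength_nm, alpha, beta, reference_nm = 550) {
  if (alpha < 0) {
    rlang::abort("`alpha` must be non-negative.",
                 class = "hb_error_parameter")
  }
  alpha * (wavelength_nm / reference_nm)^(-beta)
}

#' Fitting options for the attenuation decomposition
#'
#' @param beta_starts Multi-start values for the scattering power beta; the
#'   start with the lowest final sum of squares wins.
#' @param beta_max Upper box bound on beta.
#' @param ftol Relative reduction tolerance on the sum of squares.
#' @param ptol Relative parameter-step tolerance.
#' @param maxfev Maximum residual evaluations per start.
#' @param norm_band Two-element band (nm) whose mu_t mean scales the
#'   reported normalized residual.
#' @return A list of class `hb_fit_options`.
#' @export
fit_options <- function(beta_starts = c(0.5, 1.5, 3), beta_max = 10,
                        ftol = 1e-10, ptol = 1e-8, maxfev = 2000,
                        norm_band = c(525, 585)) {
  structure(list(beta_starts = beta_starts, beta_max = beta_max,
                 ftol = ftol, ptol = ptol, maxfev = maxfev,
                 norm_band = norm_band),
            class = "hb_fit_options")
}

#' Decompose an attenuation spectrum into chromophores plus scattering
#'
#' Fits the five-parameter model
#' mu_t(lambda) = f_Hb mu_a,Hb + f_HbO2 mu_a,HbO2 + f_metHb mu_a,metHb
#'              + alpha (lambda/550)^(-beta)
#' to a measured total attenuation spectrum by nonlinear least squares over
#' the fit band, under box constraints f >= 0, alpha >= 0,
#' 0 <= beta <= `beta_max`. The fractions f are unitless scalings of the
#' reference spectra (1 = the concentration the references were tabulated
#' for). Minimization is multi-start: at each starting beta the four linear
#' amplitudes are initialized by a non-negative least-squares solve, then
#' all five parameters are refined by Levenberg-Marquardt; the start with
#' the lowest final sum of squares is kept.
#'
#' @param mu_t Total attenuation spectrum tibble (mm^-1). Resampled onto
#'   `band` if not already on its grid.
#' @param basis A [chromophore_basis()] (resampled onto `band` as needed).
#' @param band The fit band, an [analysis_grid()]; defaults to 465 points
#'   on 490-620 nm.
#' @param options An [fit_options()] list.
#' @return An object of class `hb_fit`; see [tidy.hb_fit()] and
#'   [glance.hb_fit()] for tabular views. Key elements: `fractions` (named
#'   f_Hb, f_HbO2, f_metHb), `alpha`, `beta`, `so2` (percent, `NA` when
#'   undefined), `residual` and `norm_residual` spectra,
#'   `rms_norm_residual`, `sse`, `basis_name`, `band`.
#' @examples
#' grid <- analysis_grid(n_points = 48)
#' basis <- make_synthetic_basis(grid)
#' truth <- phantom_truth(f_Hb = 0.1, f_HbO2 = 0.9, f_metHb = 0,
#'                        alpha = 0.2, beta = 1.3, basis = basis)
#' fit <- fit_attenuation(forward_mu_t(truth), basis, grid)
#' compute_so2(fit)
#' @export
fit_attenuation <- function(mu_t, basis, band = analysis_grid(),
                            options = fit_options()) {
  fit_decomposition(mu_t, basis, band, options, fit_scattering = TRUE)
}

#' Decompose an absorption spectrum into hemoglobin species only
#'
#' Same model and solver as [fit_attenuation()] but with the scattering
#' term fixed to zero (alpha = 0), for absorption spectra obtained from
#' reflectance instruments where scattering has already been separated out.
#' Because the remaining model is linear, the constrained optimum is found
#' directly by non-negative least squares.
#'
#' @inheritParams fit_attenuation
#' @param mu_a Absorption spectrum tibble (mm^-1 or band-normalized).
#' @return An `hb_fit` with `alpha = 0` and `beta = NA`.
#' @export
fit_absorption <- function(mu_a, basis, band = analysis_grid(),
                           options = fit_options()) {
  fit_decomposition(mu_a, basis, band, options, fit_scattering = FALSE)
}

# Shared fitting engine. With fit_scattering = FALSE the problem is a
# 3-parameter NNLS and is solved exactly in one shot.
fit_decomposition <- function(spec, basis, band, options, fit_scattering) {
  validate_spectrum(spec)
  stopifnot(inherits(band, "analysis_grid"))
  wl <- grid_wavelengths(band)
  if (nrow(spec) != band$n_points ||
      max(abs(spec$wavelength_nm - wl)) > 1e-9) {
    spec <- resample_spectrum(spec, band)
  }
  if (nrow(basis) != band$n_points ||
      max(abs(basis$wavelength_nm - wl)) > 1e-9) {
    basis <- resample_basis(basis, band)
  }
  A <- basis_matrix(basis)
  y <- spec$value
  cond <- kappa(A, exact = FALSE)
  if (!is.finite(cond) || cond > 1e6) {
    rlang::warn("Basis components are near-collinear on the fit band.",
                class = "hb_warning_identifiability")
  }

  if (fit_scattering) {
    sol <- solve_chromophore_scattering(A, y, wl, options)
  } else {
    amp <- pracma::lsqnonneg(A, y)$x
    sol <- list(theta = c(amp, 0, NA_real_),
                sse = sum((y - A %*% amp)^2), converged = TRUE)
  }
  theta <- sol$theta
  fractions <- c(f_Hb = theta[1], f_HbO2 = theta[2], f_metHb = theta[3])
  alpha <- theta[4]
  beta <- theta[5]
  mu_s <- if (fit_scattering) scattering_mu_s(wl, alpha, beta) else rep(0, length(wl))
  recon <- as.numeric(A %*% theta[1:3]) + mu_s
  residual <- spectrum_tbl(wl, y - recon, spectrum_unit(spec))
  norm_res <- normalize_residual(residual, spec,
                                 options$norm_band[1], options$norm_band[2])
  hb_total <- fractions[["f_Hb"]] + fractions[["f_HbO2"]]
  so2 <- if (hb_total > 0) 100 * fractions[["f_HbO2"]] / hb_total else NA_real_

  structure(list(
    fractions = fractions,
    alpha = alpha,
    beta = beta,
    so2 = so2,
    scattering = list(alpha = alpha, beta = beta, reference_nm = 550),
    mu_t = spec,
    reconstruction = spectrum_tbl(wl, recon, spectrum_unit(spec)),
    residual = residual,
    norm_residual = norm_res,
    rms_norm_residual = rms_residual(norm_res),
    sse = sol$sse,
    converged = sol$converged,
    basis = basis,
    basis_name = basis_name(basis),
    band = band,
    method = if (fit_scattering) "attenuation" else "absorption"
  ), class = "hb_fit")
}

# Multi-start box-constrained Levenberg-Marquardt for the 5-parameter
# chromophore + power-law-scattering model.
solve_chromophore_scattering <- function(A, y, wl, options) {
  w550 <- wl / 550
  resid_fun <- function(theta) {
    y - as.numeric(A %*% theta[1:3]) - theta[4] * w550^(-theta[5])
  }
  lower <- c(0, 0, 0, 0, 0)
  upper <- c(Inf, Inf, Inf, Inf, options$beta_max)
  ctrl <- minpack.lm::nls.lm.control(ftol = options$ftol,
                                     ptol = options$ptol,
                                     maxfev = options$maxfev)
  best <- NULL
  for (b0 in options$beta_starts) {
    amp0 <- pracma::lsqnonneg(cbind(A, w550^(-b0)), y)$x
    start <- pmin(pmax(c(amp0, b0), lower), upper)
    fit <- try(minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                                  fn = resid_fun, control = ctrl),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(theta = as.numeric(fit$par), sse = sse,
                   converged = fit$info %in% 1:4)
    }
  }
  if (is.null(best)) {
    rlang::abort("All solver starts failed.", class = "hb_error_convergence")
  }
  if (!best$converged) {
    rlang::warn("Solver reported non-convergence; best candidate returned.",
                class = "hb_warning_convergence")
  }
  best
}

#' Hemoglobin oxygen saturation of a fit
#'
#' SO2 = 100 * f_HbO2 / (f_Hb + f_HbO2), in percent. Methemoglobin does not
#' enter: it cannot carry oxygen.
#'
#' @param x An `hb_fit`, or a numeric vector with named elements `f_Hb` and
#'   `f_HbO2`.
#' @return SO2 in percent, in \[0, 100\].
#' @export
compute_so2 <- function(x) {
  f <- if (inherits(x, "hb_fit")) x$fractions else x
  denom <- f[["f_Hb"]] + f[["f_HbO2"]]
  if (!is.finite(denom) || denom <= 0) {
    rlang::abort("SO2 undefined: f_Hb + f_HbO2 is zero.",
                 class = "hb_error_degenerate")
  }
  100 * f[["f_HbO2"]] / denom
}

#' Scattering-corrected hemoglobin absorption spectrum
#'
#' Removes the fitted methemoglobin and scattering contributions from the
#' measured total attenuation, leaving the absorption attributable to oxy-
#' plus deoxyhemoglobin (and the fit residual):
#' mu_a,Hb+HbO2(lambda) = mu_t - f_metHb mu_a,metHb - mu_s(lambda).
#'
#' @param mu_t Measured total attenuation spectrum on the fit-band grid.
#' @param fit An `hb_fit` from [fit_attenuation()].
#' @param basis The [chromophore_basis()] used in the fit (defaults to the
#'   one stored in the fit).
#' @return Spectrum tibble in absorption units.
#' @export
corrected_hemoglobin_absorption <- function(mu_t, fit, basis = fit$basis) {
  validate_spectrum(mu_t)
  check_shared_grid(mu_t, basis)
  mu_s <- scattering_mu_s(mu_t$wavelength_nm, fit$alpha,
                          if (is.na(fit$beta)) 0 else fit$beta)
  value <- mu_t$value - fit$fractions[["f_metHb"]] * basis$metHb - mu_s
  spectrum_tbl(mu_t$wavelength_nm, value, "absorption_mm1")
}

#' Scattering contribution to the total attenuation
#'
#' Ratio of the summed fitted scattering spectrum to the summed measured
#' attenuation over the fit band.
#'
#' @param fit An `hb_fit`.
#' @param mu_t Attenuation spectrum on the fit-band grid (defaults to the
#'   spectrum stored in the fit).
#' @return Fraction in \[0, 1\].
#' @export
scattering_fraction <- function(fit, mu_t = fit$mu_t) {
  validate_spectrum(mu_t)
  tot <- sum(mu_t$value)
  if (abs(tot) < .Machine$double.eps * 100) {
    rlang::abort("Total attenuation sums to zero.",
                 class = "hb_error_degenerate")
  }
  mu_s <- scattering_mu_s(mu_t$wavelength_nm, fit$alpha,
                          if (is.na(fit$beta)) 0 else fit$beta)
  sum(mu_s) / tot
}

#' Methemoglobin share of total hemoglobin
#'
#' f_metHb / (f_Hb + f_HbO2 + f_metHb).
#'
#' @param x An `hb_fit`, or a named numeric vector with `f_Hb`, `f_HbO2`,
#'   `f_metHb`.
#' @return Fraction in \[0, 1\].
#' @export
methb_fraction <- function(x) {
  f <- if (inherits(x, "hb_fit")) x$fractions else x
  denom <- f[["f_Hb"]] + f[["f_HbO2"]] + f[["f_metHb"]]
  if (!is.finite(denom) || denom <= 0) {
    rlang::abort("metHb fraction undefined: all fractions are zero.",
                 class = "hb_error_degenerate")
  }
  f[["f_metHb"]] / denom
}

#' @export
print.hb_fit <- function(x, ...) {
  cat(sprintf("<hb_fit> %s decomposition, basis '%s'\n",
              x$method, x$basis_name))
  cat(sprintf("  f_Hb = %.4g, f_HbO2 = %.4g, f_metHb = %.4g\n",
              x$fractions[["f_Hb"]], x$fractions[["f_HbO2"]],
              x$fractions[["f_metHb"]]))
  if (x$method == "attenuation") {
    cat(sprintf("  scattering: alpha = %.4g mm^-1 at 550 nm, beta = %.3g\n",
                x$alpha, x$beta))
  }
  so2 <- if (is.na(x$so2)) "undefined" else sprintf("%.1f%%", x$so2)
  cat(sprintf("  SO2 = %s, rms normalized residual = %.3g\n",
              so2, x$rms_norm_residual))
  invisible(x)
}

#' Tidy a hemoglobin decomposition fit
#'
#' @param x An `hb_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter (`term`, `estimate`).
#' @export
tidy.hb_fit <- function(x, ...) {
  tibble::tibble(
    term = c("f_Hb", "f_HbO2", "f_metHb", "alpha", "beta"),
    estimate = unname(c(x$fractions, x$alpha, x$beta))
  )
}

#' One-row summary of a hemoglobin decomposition fit
#'
#' @param x An `hb_fit`.
#' @param ... Unused.
#' @return A one-row tibble: basis, SO2, rms normalized residual, sum of
#'   squares, scattering and metHb summary fractions, convergence flag.
#' @export
glance.hb_fit <- function(x, ...) {
  tibble::tibble(
    basis = x$basis_name,
    method = x$method,
    so2 = x$so2,
    rms_norm_residual = x$rms_norm_residual,
    sse = x$sse,
    scattering_fraction = if (x$method == "attenuation")
      scattering_fraction(x) else 0,
    methb_fraction = methb_fraction(x),
    converged = x$converged
  )
}
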