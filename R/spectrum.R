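#' Known spectrum units
#'
#' Unit labels used throughout the package. Transmission intensities are in
#' detector counts; attenuation/absorption coefficients in mm^-1; tabulated
#' molar (decadic) extinction coefficients in L mol^-1 cm^-1.
#'
#' @keywords internal
#' @noRd
spectrum_units <- c(
  "attenuation_mm1", "absorption_mm1", "extinction_Lmol1cm1",
  "intensity_counts", "dimensionless"
)

#' Build a spectrum tibble
#'
#' A spectrum is a tibble with a strictly increasing `wavelength_nm` column
#' and a `value` column; the physical unit is carried in the `"unit"`
#' attribute. Every analysis function in the package accepts any data frame
#' with these two columns, so spectra survive ordinary dplyr manipulation.
#'
#' @param wavelength_nm Strictly increasing numeric vector of wavelengths (nm).
#' @param value Numeric vector of the same length.
#' @param unit One of `"attenuation_mm1"`, `"absorption_mm1"`,
#'   `"extinction_Lmol1cm1"`, `"intensity_counts"`, `"dimensionless"`.
#' @return A tibble with columns `wavelength_nm`, `value` and attribute
#'   `"unit"`.
#' @examples
#' spectrum_tbl(500:510, runif(11), "absorption_mm1")
#' @export
spectrum_tbl <- function(wavelength_nm, value, unit = "dimensionless") {
  unit <- match.arg(unit, spectrum_units)
  spec <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                         value = as.numeric(value))
  validate_spectrum(spec)
  attr(spec, "unit") <- unit
  spec
}

#' Unit of a spectrum tibble
#'
#' @param spec A spectrum tibble.
#' @return The `"unit"` attribute, or `"dimensionless"` if none is set.
#' @export
spectrum_unit <- function(spec) {
  attr(spec, "unit") %||% "dimensionless"
}

# Invariant checks shared by all consumers: two columns, strictly increasing
# grid of length >= 2, finite values.
validate_spectrum <- function(spec, require_positive = FALSE,
                              arg = deparse(substitute(spec))) {
  if (!is.data.frame(spec) ||
      !all(c("wavelength_nm", "value") %in% names(spec))) {
    rlang::abort(paste0("`", arg, "` must be a data frame with columns ",
                        "`wavelength_nm` and `value`."),
                 class = "hb_error_spectrum")
  }
  wl <- spec$wavelength_nm
  if (length(wl) < 2L || any(diff(wl) <= 0)) {
    rlang::abort(paste0("`", arg, "` needs >= 2 strictly increasing ",
                        "wavelengths."), class = "hb_error_spectrum")
  }
  if (!all(is.finite(spec$value))) {
    rlang::abort(paste0("`", arg, "` contains non-finite values."),
                 class = "hb_error_spectrum")
  }
  if (require_positive && any(spec$value <= 0)) {
    rlang::abort(paste0("`", arg, "` must be strictly positive."),
                 class = "hb_error_spectrum")
  }
  invisible(spec)
}

# Grids must agree exactly for pointwise arithmetic between spectra.
check_shared_grid <- function(a, b, tol = 1e-9) {
  if (nrow(a) != nrow(b) ||
      max(abs(a$wavelength_nm - b$wavelength_nm)) > tol) {
    rlang::abort("Spectra are not on a shared wavelength grid.",
                 class = "hb_error_grid")
  }
  invisible(TRUE)
}

#' Define an evenly spaced analysis wavelength grid
#'
#' The default reproduces the fit band used throughout the package: 465
#' evenly spaced points on 490-620 nm (about 0.28 nm spacing), which also
#' fixes the degrees of freedom N = 465 of the residual F-test.
#'
#' @param lower_nm,upper_nm Band edges in nm, `lower_nm < upper_nm`.
#' @param n_points Number of grid points, at least 2.
#' @return An object of class `analysis_grid`.
#' @examples
#' grid_wavelengths(analysis_grid())[1:3]
#' @export
analysis_grid <- function(lower_nm = 490, upper_nm = 620, n_points = 465) {
  if (!is.numeric(lower_nm) || !is.numeric(upper_nm) || lower_nm >= upper_nm) {
    rlang::abort("`lower_nm` must be smaller than `upper_nm`.",
                 class = "hb_error_parameter")
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L) {
    rlang::abort("`n_points` must be at least 2.",
                 class = "hb_error_parameter")
  }
  structure(list(lower_nm = lower_nm, upper_nm = upper_nm,
                 n_points = n_points),
            class = "analysis_grid")
}

#' Wavelengths of an analysis grid
#'
#' @param grid An [analysis_grid()].
#' @return Numeric vector of `n_points` evenly spaced wavelengths.
#' @export
grid_wavelengths <- function(grid) {
  stopifnot(inherits(grid, "analysis_grid"))
  seq(grid$lower_nm, grid$upper_nm, length.out = grid$n_points)
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("<analysis_grid> %g-%g nm, %d points (%.3f nm spacing)\n",
              x$lower_nm, x$upper_nm, x$n_points,
              (x$upper_nm - x$lower_nm) / (x$n_points - 1)))
  invisible(x)
}

#' Convert molar extinction to an absorption coefficient
#'
#' Converts tabulated decadic molar extinction coefficients
#' (L mol^-1 cm^-1) to absorption coefficients in mm^-1 for a hemoglobin
#' solution of known mass concentration:
#' mu_a = ln(10) * eps * C / MW, then cm^-1 -> mm^-1. The whole-blood
#' convention is C = 150 g/L and MW = 64500 g/mol.
#'
#' @param eps Spectrum tibble of decadic molar extinction coefficients.
#' @param concentration_g_per_L Hemoglobin mass concentration (g/L), > 0.
#' @param molecular_weight_g_per_mol Hemoglobin molar mass (g/mol), > 0.
#' @return Spectrum tibble in `absorption_mm1` units on the same grid.
#' @examples
#' eps <- spectrum_tbl(c(500, 550, 600), c(30000, 50000, 4000),
#'                     "extinction_Lmol1cm1")
#' convert_extinction_to_absorption(eps, 150, 64500)
#' @export
convert_extinction_to_absorption <- function(eps,
                                             concentration_g_per_L = 150,
                                             molecular_weight_g_per_mol = 64500) {
  validate_spectrum(eps)
  if (!is.numeric(concentration_g_per_L) || concentration_g_per_L <= 0 ||
      !is.numeric(molecular_weight_g_per_mol) ||
      molecular_weight_g_per_mol <= 0) {
    rlang::abort("Concentration and molecular weight must be positive.",
                 class = "hb_error_parameter")
  }
  molarity <- concentration_g_per_L / molecular_weight_g_per_mol  # mol/L
  mu_a_cm <- log(10) * eps$value * molarity                       # cm^-1
  spectrum_tbl(eps$wavelength_nm, mu_a_cm / 10, "absorption_mm1")
}

#' Resample a spectrum onto an analysis grid
#'
#' Linear interpolation onto the grid's evenly spaced points; no smoothing
#' and no extrapolation (the grid must lie inside the spectrum's range).
#'
#' @param spec Spectrum tibble.
#' @param grid An [analysis_grid()].
#' @return Spectrum tibble on the grid's wavelengths; unit preserved.
#' @export
resample_spectrum <- function(spec, grid) {
  validate_spectrum(spec)
  wl_out <- grid_wavelengths(grid)
  rng <- range(spec$wavelength_nm)
  if (wl_out[1] < rng[1] - 1e-9 || wl_out[length(wl_out)] > rng[2] + 1e-9) {
    rlang::abort(sprintf(
      "Grid %g-%g nm extends beyond the spectrum's range %g-%g nm.",
      wl_out[1], wl_out[length(wl_out)], rng[1], rng[2]),
      class = "hb_error_range")
  }
  out <- stats::approx(spec$wavelength_nm, spec$value, xout = wl_out,
                       method = "linear", rule = 1)$y
  spectrum_tbl(wl_out, out, spectrum_unit(spec))
}

# Indices of grid points inside a closed wavelength band.
band_index <- function(wavelength_nm, band_lower_nm, band_upper_nm) {
  which(wavelength_nm >= band_lower_nm - 1e-9 &
          wavelength_nm <= band_upper_nm + 1e-9)
}

# Mean of a spectrum's values over a closed band; errors if the band misses
# the grid entirely.
band_mean <- function(spec, band_lower_nm, band_upper_nm) {
  idx <- band_index(spec$wavelength_nm, band_lower_nm, band_upper_nm)
  if (length(idx) == 0L) {
    rlang::abort(sprintf("Band %g-%g nm contains no grid points.",
                         band_lower_nm, band_upper_nm),
                 class = "hb_error_band")
  }
  mean(spec$value[idx])
}

#' Normalize a spectrum by its mean over a wavelength band
#'
#' Divides every value by the average of the values at grid points inside
#' the closed band. The default band, 525-585 nm, is the oxyhemoglobin
#' "alpha band" used to put spectra from samples of different hemoglobin
#' concentration on a common scale.
#'
#' @param spec Spectrum tibble.
#' @param band_lower_nm,band_upper_nm Closed band edges (nm).
#' @return Dimensionless spectrum whose band mean is 1.
#' @export
normalize_band <- function(spec, band_lower_nm = 525, band_upper_nm = 585) {
  validate_spectrum(spec)
  m <- band_mean(spec, band_lower_nm, band_upper_nm)
  if (abs(m) < .Machine$double.eps * 100) {
    rlang::abort("Band mean is zero; normalization is degenerate.",
                 class = "hb_error_degenerate")
  }
  spectrum_tbl(spec$wavelength_nm, spec$value / m, "dimensionless")
}

#' Normalize a residual spectrum by the band mean of the attenuation
#'
#' The fit residual is scaled by the 525-585 nm band mean of the total
#' attenuation mu_t -- not of the residual itself -- so residual magnitudes
#' are comparable across samples of different hemoglobin concentration.
#'
#' @param residual Residual spectrum tibble.
#' @param mu_t Total attenuation spectrum on the same grid.
#' @param band_lower_nm,band_upper_nm Closed band edges (nm).
#' @return Dimensionless spectrum.
#' @export
normalize_residual <- function(residual, mu_t,
                               band_lower_nm = 525, band_upper_nm = 585) {
  validate_spectrum(residual)
  validate_spectrum(mu_t)
  check_shared_grid(residual, mu_t)
  m <- band_mean(mu_t, band_lower_nm, band_upper_nm)
  if (abs(m) < .Machine$double.eps * 100) {
    rlang::abort("Band mean of mu_t is zero; normalization is degenerate.",
                 class = "hb_error_degenerate")
  }
  spectrum_tbl(residual$wavelength_nm, residual$value / m, "dimensionless")
}

#' Read a two-column spectrum file
#'
#' Tab-delimited text with two columns: `wavelength_nm`, then a value column
#' whose header names the unit (one of the labels in the package's unit
#' vocabulary, e.g. `absorption_mm1`).
#'
#' @param path File path.
#' @return Spectrum tibble with the unit taken from the header.
#' @export
read_spectrum <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (ncol(df) != 2L || names(df)[1] != "wavelength_nm") {
    rlang::abort(paste0("Expected two columns (wavelength_nm, <unit>) in ",
                        path), class = "hb_error_io")
  }
  unit <- names(df)[2]
  if (!unit %in% spectrum_units) {
    rlang::abort(sprintf(
      "Unit header '%s' in %s is not one of: %s.", unit, path,
      paste(spectrum_units, collapse = ", ")), class = "hb_error_unit")
  }
  spectrum_tbl(df[[1]], df[[2]], unit)
}

#' Write a spectrum to a two-column file
#'
#' Inverse of [read_spectrum()]: the value column's header is the unit.
#'
#' @param spec Spectrum tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  validate_spectrum(spec)
  out <- tibble::tibble(wavelength_nm = spec$wavelength_nm)
  out[[spectrum_unit(spec)]] <- spec$value
  readr::write_tsv(out, path)
  invisible(path)
}
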