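#' Build a multi-pathlength transmission series
#'
#' A transmission series holds collimated-transmission intensity spectra
#' I(lambda, d) collected at several optical pathlengths d through the same
#' sample, in tidy long form: one row per (wavelength, pathlength) cell.
#'
#' @param data A data frame with columns `wavelength_nm`, `pathlength_mm`
#'   and `intensity` (detector counts); an optional logical `excluded`
#'   column flags cells to leave out of the regression.
#' @return A tibble of class `transmission_series` with an `excluded`
#'   column (defaulting to `FALSE`).
#' @export
transmission_series <- function(data) {
  need <- c("wavelength_nm", "pathlength_mm", "intensity")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    rlang::abort("Need columns wavelength_nm, pathlength_mm, intensity.",
                 class = "hb_error_transmission")
  }
  out <- tibble::as_tibble(data)
  if (!"excluded" %in% names(out)) out$excluded <- FALSE
  d <- unique(out$pathlength_mm)
  if (length(d) < 2L) {
    rlang::abort("At least 2 distinct pathlengths are required.",
                 class = "hb_error_transmission")
  }
  # every pathlength must sample the same wavelength grid
  n_wl <- dplyr::n_distinct(out$wavelength_nm)
  counts <- dplyr::count(out, .data$pathlength_mm)
  if (any(counts$n != n_wl)) {
    rlang::abort("All pathlengths must share one wavelength grid.",
                 class = "hb_error_transmission")
  }
  class(out) <- c("transmission_series", class(out))
  out
}

#' Flag intensities outside the detector's usable range
#'
#' Cells with intensity below `floor_counts` (noise floor / dropout) or
#' above `ceiling_counts` (saturation) are marked `excluded` so the
#' Beer-Lambert regression skips them; nothing else changes.
#'
#' @param series A [transmission_series()].
#' @param floor_counts,ceiling_counts Usable intensity range,
#'   `floor_counts < ceiling_counts`.
#' @return The series with its `excluded` column updated.
#' @export
mask_saturated <- function(series, floor_counts = 0,
                           ceiling_counts = Inf) {
  series <- transmission_series(series)
  if (floor_counts >= ceiling_counts) {
    rlang::abort("`floor_counts` must be below `ceiling_counts`.",
                 class = "hb_error_parameter")
  }
  dplyr::mutate(series, excluded = .data$excluded |
                  .data$intensity < floor_counts |
                  .data$intensity > ceiling_counts)
}

#' Estimate the total attenuation spectrum from a transmission series
#'
#' Per-wavelength inverse Beer-Lambert regression: for each wavelength,
#' ordinary least squares of -ln I(lambda, d) on pathlength d gives the
#' slope mu_t(lambda) (mm^-1) and the intercept -ln I(lambda, d0), i.e. the
#' log effective incident intensity. The zero-pathlength spectrum enters as
#' an ordinary regression point; no weighting is applied.
#'
#' Non-positive intensities cannot enter the log and are excluded with a
#' warning. Wavelengths left with fewer than two usable points get `NA`
#' estimates and a warning.
#'
#' @param series A [transmission_series()].
#' @return A tibble of class `attenuation_estimate` with columns
#'   `wavelength_nm`, `mu_t` (mm^-1), `log_I0` (ln counts),
#'   `rmse` (per-wavelength residual rmse of the log-linear fit) and
#'   `n_used` (regression points used).
#' @examples
#' truth <- phantom_preset("lb", grid = analysis_grid(n_points = 24))
#' series <- forward_transmission(truth)
#' estimate_attenuation(series)
#' @export
estimate_attenuation <- function(series) {
  series <- transmission_series(series)
  bad <- !series$excluded & series$intensity <= 0
  if (any(bad)) {
    rlang::warn(sprintf(
      "%d non-positive intensity value(s) excluded from the regression.",
      sum(bad)), class = "hb_warning_masked")
    series$excluded[bad] <- TRUE
  }

  if (!any(series$excluded)) {
    out <- ols_all_wavelengths(series)
  } else {
    out <- ols_per_wavelength(series)
  }

  if (anyNA(out$mu_t)) {
    rlang::warn(sprintf(
      "Attenuation undefined at %d wavelength(s) (<2 usable points).",
      sum(is.na(out$mu_t))), class = "hb_warning_undefined")
  }
  class(out) <- c("attenuation_estimate", class(out))
  out
}

# Vectorized OLS over all wavelengths at once: valid when no cell is
# excluded, so every wavelength shares the same pathlength design.
ols_all_wavelengths <- function(series) {
  wide <- series |>
    dplyr::select("wavelength_nm", "pathlength_mm", "intensity") |>
    tidyr::pivot_wider(names_from = "pathlength_mm",
                       values_from = "intensity") |>
    dplyr::arrange(.data$wavelength_nm)
  wl <- wide$wavelength_nm
  Y <- -log(as.matrix(wide[, -1, drop = FALSE]))   # wavelength x pathlength
  d <- as.numeric(colnames(wide)[-1])
  dc <- d - mean(d)
  slope <- as.numeric(Y %*% dc) / sum(dc^2)
  intercept <- rowMeans(Y) - slope * mean(d)
  res <- Y - (outer(slope, d) + intercept)
  tibble::tibble(wavelength_nm = wl, mu_t = slope, log_I0 = -intercept,
                 rmse = sqrt(rowMeans(res^2)), n_used = length(d))
}

# Per-wavelength loop honouring exclusion flags (slower, general case).
ols_per_wavelength <- function(series) {
  fit_one <- function(df) {
    use <- !df$excluded
    n <- sum(use)
    if (n < 2L || length(unique(df$pathlength_mm[use])) < 2L) {
      return(tibble::tibble(mu_t = NA_real_, log_I0 = NA_real_,
                            rmse = NA_real_, n_used = n))
    }
    d <- df$pathlength_mm[use]
    y <- -log(df$intensity[use])
    dbar <- mean(d); ybar <- mean(y)
    slope <- sum((d - dbar) * (y - ybar)) / sum((d - dbar)^2)
    intercept <- ybar - slope * dbar      # = -ln I(lambda, d0)
    res <- y - (slope * d + intercept)
    tibble::tibble(mu_t = slope, log_I0 = -intercept,
                   rmse = sqrt(mean(res^2)), n_used = n)
  }
  series |>
    dplyr::group_by(.data$wavelength_nm) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$wavelength_nm)
}

#' Extract the attenuation spectrum from an estimate
#'
#' @param estimate An [estimate_attenuation()] result.
#' @return Spectrum tibble of mu_t in `attenuation_mm1` units (wavelengths
#'   with undefined estimates dropped).
#' @export
attenuation_spectrum <- function(estimate) {
  keep <- !is.na(estimate$mu_t)
  spectrum_tbl(estimate$wavelength_nm[keep], estimate$mu_t[keep],
               "attenuation_mm1")
}

#' Read a transmission series from a wide delimited file
#'
#' First column `wavelength_nm`; every remaining column is one pathlength,
#' named by its value in mm (e.g. `0`, `0.025`, `0.05`, ...).
#'
#' @param path File path (tab-delimited).
#' @return A [transmission_series()].
#' @export
read_transmission <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (names(df)[1] != "wavelength_nm" || ncol(df) < 3L) {
    rlang::abort(paste0("Expected wavelength_nm plus >= 2 pathlength ",
                        "columns in ", path), class = "hb_error_io")
  }
  d <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(d)) {
    rlang::abort("Pathlength column names must be numeric (mm).",
                 class = "hb_error_io")
  }
  long <- tidyr::pivot_longer(df, -"wavelength_nm",
                              names_to = "pathlength_mm",
                              values_to = "intensity") |>
    dplyr::mutate(pathlength_mm = as.numeric(.data$pathlength_mm)) |>
    dplyr::arrange(.data$pathlength_mm, .data$wavelength_nm)
  transmission_series(long)
}

#' Write a transmission series as a wide delimited file
#'
#' Inverse of [read_transmission()]. The `excluded` flag is not persisted;
#' masking is re-derivable from the intensity range.
#'
#' @param series A [transmission_series()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_transmission <- function(series, path) {
  series <- transmission_series(series)
  wide <- series |>
    dplyr::select("wavelength_nm", "pathlength_mm", "intensity") |>
    dplyr::mutate(pathlength_mm = as.character(.data$pathlength_mm)) |>
    tidyr::pivot_wider(names_from = "pathlength_mm",
                       values_from = "intensity") |>
    dplyr::arrange(.data$wavelength_nm)
  readr::write_tsv(wide, path)
  invisible(path)
}
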