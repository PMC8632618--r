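#' Plot a set of spectra on one panel
#'
#' @param spectra Named list of spectrum tibbles on any grids.
#' @param normalize If `TRUE`, band-normalize each spectrum (525-585 nm)
#'   before plotting so shapes are comparable.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, normalize = FALSE) {
  df <- purrr::imap_dfr(spectra, function(s, nm) {
    if (normalize) s <- normalize_band(s)
    tibble::tibble(wavelength_nm = s$wavelength_nm, value = s$value,
                   spectrum = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$value,
                                   colour = .data$spectrum)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = if (normalize) "normalized value" else "value") +
    ggplot2::theme_minimal()
}

#' Plot a fitted decomposition
#'
#' Top panel: measured spectrum, full model reconstruction and the fitted
#' per-component contributions. Bottom panel: the normalized residual --
#' the diagnostic in which a mismatched reference basis shows up as a
#' systematic (non-white) shape.
#'
#' @param object An `hb_fit`.
#' @param ... Unused.
#' @return A ggplot object (faceted).
#' @export
autoplot.hb_fit <- function(object, ...) {
  wl <- object$mu_t$wavelength_nm
  A <- basis_matrix(object$basis)
  comp <- tibble::tibble(
    wavelength_nm = rep(wl, 5),
    value = c(object$mu_t$value, object$reconstruction$value,
              A[, "Hb"] * object$fractions[["f_Hb"]],
              A[, "HbO2"] * object$fractions[["f_HbO2"]],
              A[, "metHb"] * object$fractions[["f_metHb"]] +
                scattering_mu_s(wl, object$alpha,
                                if (is.na(object$beta)) 0 else object$beta)),
    curve = rep(c("measured", "model", "Hb", "HbO2", "metHb + scattering"),
                each = length(wl)),
    panel = "fit"
  )
  res <- tibble::tibble(wavelength_nm = wl,
                        value = object$norm_residual$value,
                        curve = "normalized residual", panel = "residual")
  df <- dplyr::bind_rows(comp, res)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(title = sprintf("Decomposition under basis '%s'",
                                  object$basis_name),
                  x = "wavelength (nm)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the residual spectra of a basis comparison
#'
#' Overlays the normalized residual of every fitted basis; a basis that
#' matches the sample's true chromophore shapes leaves white, small
#' residuals, while a mismatched one leaves a visibly structured curve.
#'
#' @param object An `hb_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hb_comparison <- function(object, ...) {
  df <- purrr::imap_dfr(object$fits, function(f, nm) {
    tibble::tibble(wavelength_nm = f$norm_residual$wavelength_nm,
                   value = f$norm_residual$value, basis = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength_nm, .data$value,
                                   colour = .data$basis)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "normalized residual") +
    ggplot2::theme_minimal()
}
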