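#' Root-mean-square of a (normalized) residual spectrum
#'
#' @param residual Spectrum tibble or bare numeric vector.
#' @return sqrt(mean(value^2)).
#' @export
rms_residual <- function(residual) {
  v <- if (is.data.frame(residual)) residual$value else residual
  if (length(v) == 0L) {
    rlang::abort("Residual is empty.", class = "hb_error_degenerate")
  }
  sqrt(mean(v^2))
}

#' F-test on the squared rms residuals of two fits
#'
#' Treats the per-wavelength residuals as independent normal variables, so
#' each squared rms is chi-square(N)-scaled and their ratio is
#' F(N, N)-distributed, N being the number of fit-band wavelengths (no
#' reduction for fitted parameters). The larger squared rms goes in the
#' numerator, so the test is two-sided at level `p` via the upper-p/2
#' quantile: with N = 465 and p = 0.01 the critical value is 1.27.
#'
#' @param rms_a,rms_b Positive rms residuals of the two fits.
#' @param n Degrees of freedom: number of fit-band wavelength samples.
#' @param p Significance level, in (0, 0.5).
#' @return A one-row tibble: `f_ratio`, `dof`, `critical`, `significant`.
#' @examples
#' f_compare(0.018, 0.0054, n = 465)
#' @export
f_compare <- function(rms_a, rms_b, n, p = 0.01) {
  if (!is.finite(rms_a) || !is.finite(rms_b) || rms_a <= 0 || rms_b <= 0) {
    rlang::abort("rms values must be positive.",
                 class = "hb_error_degenerate")
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) {
    rlang::abort("`n` must be an integer >= 2.",
                 class = "hb_error_parameter")
  }
  if (!(p > 0 && p < 0.5)) {
    rlang::abort("`p` must lie in (0, 0.5).", class = "hb_error_parameter")
  }
  f_ratio <- max(rms_a, rms_b)^2 / min(rms_a, rms_b)^2
  critical <- stats::qf(1 - p / 2, n, n)
  tibble::tibble(f_ratio = f_ratio, dof = n, critical = critical,
                 significant = f_ratio > critical)
}

#' Fit one spectrum under several reference bases and compare residuals
#'
#' Runs the chromophore decomposition under every supplied basis, collects
#' SO2 and rms normalized residuals per basis, and F-tests every pair of
#' bases on their residual magnitudes.
#'
#' @param mu_t Total attenuation (or, with `fit_fun = fit_absorption`,
#'   absorption) spectrum tibble.
#' @param bases List of [chromophore_basis()] objects (>= 1; pairwise tests
#'   need >= 2). Unnamed lists are labelled by each basis's own name.
#' @param band Fit band, an [analysis_grid()].
#' @param p Significance level for the pairwise F-tests.
#' @param label Preparation label carried into the report (e.g. "WB oxy").
#' @param fit_fun [fit_attenuation()] (default) or [fit_absorption()].
#' @param options [fit_options()] forwarded to the fits.
#' @return An object of class `hb_comparison` with elements `entries`
#'   (tibble: preparation, basis, so2, rms_norm_residual, scattering and
#'   metHb fractions), `pairwise` (tibble of F-tests) and `fits` (named
#'   list of `hb_fit` objects).
#' @export
build_comparison <- function(mu_t, bases, band = analysis_grid(), p = 0.01,
                             label = "sample", fit_fun = fit_attenuation,
                             options = fit_options()) {
  if (inherits(bases, "chromophore_basis")) bases <- list(bases)
  if (length(bases) < 1L) {
    rlang::abort("At least one basis is required.",
                 class = "hb_error_parameter")
  }
  nms <- names(bases) %||% vapply(bases, basis_name, character(1))
  if (is.null(names(bases))) names(bases) <- nms

  fits <- purrr::imap(bases, function(b, nm) {
    tryCatch(fit_fun(mu_t, b, band, options),
             error = function(e) {
               rlang::abort(sprintf("Fit under basis '%s' failed: %s",
                                    nm, conditionMessage(e)),
                            class = "hb_error_fit", parent = e)
             })
  })

  entries <- purrr::imap_dfr(fits, function(f, nm) {
    g <- glance(f)
    tibble::tibble(preparation = label, basis = nm, so2 = g$so2,
                   rms_norm_residual = g$rms_norm_residual,
                   scattering_fraction = g$scattering_fraction,
                   methb_fraction = g$methb_fraction)
  })

  pairs <- if (length(fits) >= 2L) utils::combn(names(fits), 2,
                                                simplify = FALSE) else list()
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    cmp <- f_compare(fits[[pr[1]]]$rms_norm_residual,
                     fits[[pr[2]]]$rms_norm_residual,
                     n = band$n_points, p = p)
    dplyr::mutate(cmp, preparation = label,
                  basis_a = pr[1], basis_b = pr[2], .before = 1)
  })

  structure(list(entries = entries, pairwise = pairwise, fits = fits,
                 band = band, p = p),
            class = "hb_comparison")
}

#' Assemble an optimal hybrid basis from comparison reports
#'
#' Picks the oxyhemoglobin reference from the basis with the smallest rms
#' residual on an oxygenated-dominant preparation, the deoxyhemoglobin
#' reference from the winner on a deoxygenated-dominant preparation, and
#' methemoglobin from a designated provider.
#'
#' @param bases Named list of candidate [chromophore_basis()] objects (the
#'   ones the reports were built from).
#' @param report_oxy,report_deoxy `hb_comparison` reports for an oxygenated
#'   and a deoxygenated preparation.
#' @param methb_from Name of the basis supplying metHb; defaults to the
#'   deoxy winner.
#' @param name Label for the hybrid.
#' @return A [chromophore_basis()].
#' @export
optimal_basis <- function(bases, report_oxy, report_deoxy,
                          methb_from = NULL, name = "optimal") {
  winner <- function(report) {
    e <- report$entries
    e$basis[which.min(e$rms_norm_residual)]
  }
  oxy_win <- winner(report_oxy)
  deoxy_win <- winner(report_deoxy)
  methb_from <- methb_from %||% deoxy_win
  hybrid_basis(name,
               HbO2_from = bases[[oxy_win]],
               Hb_from = bases[[deoxy_win]],
               metHb_from = bases[[methb_from]])
}

#' @export
print.hb_comparison <- function(x, ...) {
  cat(sprintf("<hb_comparison> %d basis fit(s), %d pairwise F-test(s), p = %g\n",
              nrow(x$entries), nrow(x$pairwise), x$p))
  print(x$entries)
  if (nrow(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Tidy a basis-comparison report
#'
#' @param x An `hb_comparison`.
#' @param ... Unused.
#' @return The per-basis `entries` tibble.
#' @export
tidy.hb_comparison <- function(x, ...) x$entries

#' Pairwise summary of a basis-comparison report
#'
#' @param x An `hb_comparison`.
#' @param ... Unused.
#' @return The `pairwise` F-test tibble.
#' @export
glance.hb_comparison <- function(x, ...) x$pairwise

#' Write a comparison report as delimited text
#'
#' Writes `<stem>_entries.tsv` (per-basis SO2 and rms, one row per basis,
#' mirroring a per-preparation results-table row) and
#' `<stem>_pairwise.tsv` (F-tests).
#'
#' @param report An `hb_comparison`.
#' @param stem Path stem (no extension).
#' @return The paths written, invisibly.
#' @export
write_comparison <- function(report, stem) {
  p1 <- paste0(stem, "_entries.tsv")
  p2 <- paste0(stem, "_pairwise.tsv")
  readr::write_tsv(report$entries, p1)
  readr::write_tsv(report$pairwise, p2)
  invisible(c(p1, p2))
}
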