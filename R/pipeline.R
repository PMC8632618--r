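#' Build and validate a pipeline run configuration
#'
#' A run configuration names the input files, reference-basis declarations
#' and analysis parameters of a full characterization run. It can be built
#' directly or read from YAML with [read_run_config()].
#'
#' @param input Path to the input file: a wide transmission file (see
#'   [read_transmission()]) for the collimated-transmission pipeline, or a
#'   two-column absorption spectrum (see [read_spectrum()]) for the
#'   absorption pipeline.
#' @param bases Either a named list of [chromophore_basis()] objects or a
#'   list of basis-config lists/paths (see [read_basis_config()]).
#' @param fit_band,norm_band [analysis_grid()] and two-element numeric
#'   band (nm) for fitting and normalization.
#' @param p Significance level of the pairwise F-tests, in (0, 0.5).
#' @param label Preparation label for the report.
#' @param floor_counts,ceiling_counts Detector range for [mask_saturated()].
#' @param include_optimal If `TRUE`, [run_sct_pipeline()] additionally fits
#'   a hybrid basis pairing the best-fitting HbO2 and Hb components (only
#'   meaningful with >= 2 bases on a shared grid).
#' @param seed Integer seed recorded with the run.
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @return A list of class `hb_run_config`.
#' @export
run_config <- function(input, bases, fit_band = analysis_grid(),
                       norm_band = c(525, 585), p = 0.01,
                       label = "sample", floor_counts = 0,
                       ceiling_counts = Inf, include_optimal = FALSE,
                       seed = 1, out_dir = NULL) {
  if (!(p > 0 && p < 0.5)) {
    rlang::abort("`p` must lie in (0, 0.5).", class = "hb_error_config")
  }
  stopifnot(inherits(fit_band, "analysis_grid"),
            length(norm_band) == 2L, norm_band[1] < norm_band[2])
  if (is.character(input) && !file.exists(input)) {
    rlang::abort(sprintf("Input file '%s' does not exist.", input),
                 class = "hb_error_config")
  }
  structure(list(input = input, bases = bases, fit_band = fit_band,
                 norm_band = norm_band, p = p, label = label,
                 floor_counts = floor_counts,
                 ceiling_counts = ceiling_counts,
                 include_optimal = include_optimal,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "hb_run_config")
}

#' Read a run configuration from YAML
#'
#' Expected keys: `input`, `bases` (list of basis configs, each as for
#' [read_basis_config()]), optional `fit_band` (`lower_nm`, `upper_nm`,
#' `n_points`), `norm_band` (two numbers), `p`, `label`, `floor_counts`,
#' `ceiling_counts`, `include_optimal`, `seed`, `out_dir`. Relative paths
#' are resolved against the YAML file's directory; missing files are
#' reported before any computation.
#'
#' @param path Path to the YAML file.
#' @return An `hb_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dir <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  input <- resolve(cfg$input %||%
                     rlang::abort("Config must name an `input` file.",
                                  class = "hb_error_config"))
  bases <- purrr::map(cfg$bases, function(b) {
    if (is.character(b)) read_basis_config(resolve(b))
    else read_basis_config(b, dir = dir)
  })
  names(bases) <- purrr::map_chr(bases, basis_name)
  fb <- cfg$fit_band
  fit_band <- if (is.null(fb)) analysis_grid() else
    analysis_grid(fb$lower_nm %||% 490, fb$upper_nm %||% 620,
                  fb$n_points %||% 465)
  run_config(
    input = input, bases = bases, fit_band = fit_band,
    norm_band = as.numeric(cfg$norm_band %||% c(525, 585)),
    p = cfg$p %||% 0.01, label = cfg$label %||% "sample",
    floor_counts = cfg$floor_counts %||% 0,
    ceiling_counts = cfg$ceiling_counts %||% Inf,
    include_optimal = isTRUE(cfg$include_optimal),
    seed = cfg$seed %||% 1,
    out_dir = if (!is.null(cfg$out_dir)) resolve(cfg$out_dir) else NULL
  )
}

# Stage-level log line.
hb_log <- function(...) message("[hbphantom] ", sprintf(...))

resolve_bases <- function(bases) {
  bases <- purrr::map(bases, function(b) {
    if (inherits(b, "chromophore_basis")) b else read_basis_config(b)
  })
  if (is.null(names(bases)) || any(names(bases) == "")) {
    names(bases) <- purrr::map_chr(bases, basis_name)
  }
  bases
}

#' Run the collimated-transmission characterization pipeline
#'
#' End to end: read (or accept) a multi-pathlength transmission series,
#' mask out-of-range intensities, estimate the total attenuation spectrum
#' by Beer-Lambert regression, decompose it under every declared reference
#' basis, derive SO2, scattering-corrected hemoglobin absorption and
#' composition summaries, and F-test the per-basis residual magnitudes.
#' When an output directory is configured, writes the attenuation spectrum,
#' per-basis normalized residuals and corrected absorption, and the
#' comparison tables, all as delimited text.
#'
#' @param config An [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]). `config$input` may also be a
#'   [transmission_series()] directly.
#' @return An `hb_comparison` report; artifacts on disk as configured.
#' @export
run_sct_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "hb_run_config"))
  bases <- resolve_bases(config$bases)

  series <- if (inherits(config$input, "transmission_series")) config$input
    else {
      hb_log("reading transmission series from %s", config$input)
      read_transmission(config$input)
    }
  series <- mask_saturated(series, config$floor_counts,
                           config$ceiling_counts)
  hb_log("estimating attenuation: %d wavelengths x %d pathlengths",
         dplyr::n_distinct(series$wavelength_nm),
         dplyr::n_distinct(series$pathlength_mm))
  est <- estimate_attenuation(series)
  mu_t <- resample_spectrum(attenuation_spectrum(est), config$fit_band)

  opts <- fit_options(norm_band = config$norm_band)
  hb_log("fitting %d bas(e)s on %d-point band %g-%g nm",
         length(bases), config$fit_band$n_points,
         config$fit_band$lower_nm, config$fit_band$upper_nm)
  report <- build_comparison(mu_t, bases, config$fit_band, config$p,
                             label = config$label, options = opts)

  if (config$include_optimal && length(bases) >= 2L) {
    # self-referential hybrid: winner on this sample supplies HbO2 and the
    # runner-up context decides Hb; callers comparing oxy vs deoxy samples
    # should use optimal_basis() across the two reports instead.
    opt <- optimal_basis(bases, report, report)
    report <- build_comparison(mu_t, c(bases, list(optimal = opt)),
                               config$fit_band, config$p,
                               label = config$label, options = opts)
  }

  for (nm in names(report$fits)) {
    f <- report$fits[[nm]]
    hb_log("basis '%s': f=(%.4g, %.4g, %.4g) alpha=%.4g beta=%.3g SO2=%s rms=%.3g",
           nm, f$fractions[["f_Hb"]], f$fractions[["f_HbO2"]],
           f$fractions[["f_metHb"]], f$alpha, f$beta,
           if (is.na(f$so2)) "NA" else sprintf("%.1f%%", f$so2),
           f$rms_norm_residual)
  }
  write_pipeline_artifacts(report, mu_t, config)
  report
}

#' Run the absorption-spectrum characterization pipeline
#'
#' For absorption spectra from reflectance instruments: normalizes the
#' spectrum to the oxyhemoglobin alpha band (525-585 nm by default), fits
#' the three hemoglobin species with the scattering term fixed to zero
#' under every declared basis, and reports SO2 and residual comparisons.
#' SO2 is unaffected by the normalization (it is a ratio of fractions).
#'
#' @param config An [run_config()]; `config$input` must point to a
#'   two-column spectrum in `absorption_mm1` (or `dimensionless`,
#'   if pre-normalized) units, or be such a spectrum tibble.
#' @return An `hb_comparison` report.
#' @export
run_absorption_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "hb_run_config"))
  bases <- resolve_bases(config$bases)

  mu_a <- if (is.data.frame(config$input)) config$input
    else {
      hb_log("reading absorption spectrum from %s", config$input)
      read_spectrum(config$input)
    }
  unit <- spectrum_unit(mu_a)
  if (!unit %in% c("absorption_mm1", "dimensionless")) {
    rlang::abort(sprintf(
      "Absorption pipeline expects absorption_mm1 or dimensionless input, got '%s'.",
      unit), class = "hb_error_unit")
  }
  mu_a <- resample_spectrum(mu_a, config$fit_band)
  mu_a <- normalize_band(mu_a, config$norm_band[1], config$norm_band[2])
  hb_log("fitting %d bas(e)s, absorption-only model", length(bases))
  report <- build_comparison(mu_a, bases, config$fit_band, config$p,
                             label = config$label,
                             fit_fun = fit_absorption,
                             options = fit_options(norm_band = config$norm_band))
  write_pipeline_artifacts(report, mu_a, config)
  report
}

# Plot- and audit-ready artifacts: normalized input, per-basis residuals
# and corrected absorption, entry/pairwise tables.
write_pipeline_artifacts <- function(report, spec, config) {
  dir <- config$out_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_spectrum(normalize_band(spec, config$norm_band[1],
                                config$norm_band[2]),
                 file.path(dir, "input_normalized.tsv"))
  for (nm in names(report$fits)) {
    f <- report$fits[[nm]]
    write_spectrum(f$norm_residual,
                   file.path(dir, paste0("residual_norm_", nm, ".tsv")))
    if (f$method == "attenuation") {
      corr <- corrected_hemoglobin_absorption(f$mu_t, f)
      write_spectrum(corr,
                     file.path(dir, paste0("mu_a_hb_corrected_", nm, ".tsv")))
    }
  }
  write_comparison(report, file.path(dir, "comparison"))
  hb_log("artifacts written to %s", dir)
  invisible(dir)
}

#' Simulate a phantom dataset and write it to disk
#'
#' Generates a preset phantom (see [phantom_preset()]), optionally depleted
#' to a target SO2, forward-models its transmission series, and writes the
#' series, the generating basis components and the ground truth to
#' `out_dir` in the same delimited formats the pipeline readers consume.
#'
#' @param preset `"wb"`, `"lb"` or `"a0"`.
#' @param so2 Target SO2 in percent; presets start at 97 (oxy). Values
#'   below trigger [deplete_oxygen()] with the preset's deoxy yeast
#'   scattering fraction.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param grid,noise_sigma,pathlengths_mm Forwarded to the generator.
#' @return The `phantom_truth` used, invisibly; files on disk.
#' @export
simulate_phantom <- function(preset = c("wb", "lb", "a0"), so2 = 97,
                             seed = 1, out_dir,
                             grid = analysis_grid(), noise_sigma = 0.005,
                             pathlengths_mm = seq(0, 0.3, by = 0.025)) {
  preset <- match.arg(preset)
  truth <- phantom_preset(preset, "oxy", grid, noise_sigma = noise_sigma,
                          seed = seed)
  if (so2 < 97) {
    yeast <- switch(preset, wb = 0.30, lb = 0.40, a0 = 0.25)
    truth <- deplete_oxygen(truth, so2, yeast_scattering_fraction = yeast)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  series <- forward_transmission(truth, pathlengths_mm, grid)
  write_transmission(series, file.path(out_dir, "transmission.tsv"))
  for (comp in c("Hb", "HbO2", "metHb")) {
    write_spectrum(basis_component(truth$basis, comp),
                   file.path(out_dir, paste0("basis_", comp, ".tsv")))
  }
  yaml::write_yaml(list(
    preset = preset,
    fractions = as.list(truth$fractions),
    alpha = truth$alpha, beta = truth$beta, I0 = truth$I0,
    noise_sigma = truth$noise_sigma, seed = truth$seed
  ), file.path(out_dir, "truth.yaml"))
  hb_log("simulated '%s' phantom written to %s", preset, out_dir)
  invisible(truth)
}
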