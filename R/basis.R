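#' Assemble a chromophore reference basis
#'
#' A basis bundles absorption reference spectra for the three hemoglobin
#' species -- deoxyhemoglobin (Hb), oxyhemoglobin (HbO2) and methemoglobin
#' (metHb) -- on one shared wavelength grid, under a source label such as
#' `"prahl"`, `"zijlstra"`, `"optimal"` or `"synthetic"`.
#'
#' @param name Label of the source set.
#' @param Hb,HbO2,metHb Spectrum tibbles in absorption units (mm^-1) on an
#'   identical wavelength grid, all values >= 0.
#' @return A `chromophore_basis`: a tibble with columns `wavelength_nm`,
#'   `Hb`, `HbO2`, `metHb` and attribute `"basis_name"`.
#' @export
chromophore_basis <- function(name, Hb, HbO2, metHb) {
  validate_spectrum(Hb)
  validate_spectrum(HbO2)
  validate_spectrum(metHb)
  check_shared_grid(Hb, HbO2)
  check_shared_grid(Hb, metHb)
  vals <- cbind(Hb$value, HbO2$value, metHb$value)
  if (any(vals < 0)) {
    rlang::abort("Reference absorption spectra must be non-negative.",
                 class = "hb_error_basis")
  }
  out <- tibble::tibble(wavelength_nm = Hb$wavelength_nm,
                        Hb = Hb$value, HbO2 = HbO2$value,
                        metHb = metHb$value)
  attr(out, "basis_name") <- as.character(name)
  class(out) <- c("chromophore_basis", class(out))
  out
}

#' @export
print.chromophore_basis <- function(x, ...) {
  cat(sprintf("<chromophore_basis> '%s': %d wavelengths, %g-%g nm\n",
              basis_name(x), nrow(x), min(x$wavelength_nm),
              max(x$wavelength_nm)))
  NextMethod()
}

#' Name of a chromophore basis
#'
#' @param basis A [chromophore_basis()].
#' @return The source label.
#' @export
basis_name <- function(basis) {
  attr(basis, "basis_name") %||% "unnamed"
}

#' Component spectrum of a basis
#'
#' @param basis A [chromophore_basis()].
#' @param component One of `"Hb"`, `"HbO2"`, `"metHb"`.
#' @return Spectrum tibble in absorption units.
#' @export
basis_component <- function(basis, component = c("Hb", "HbO2", "metHb")) {
  component <- match.arg(component)
  spectrum_tbl(basis$wavelength_nm, basis[[component]], "absorption_mm1")
}

# Wavelength x component absorption matrix, the design matrix of the fit.
basis_matrix <- function(basis) {
  as.matrix(as.data.frame(basis)[, c("Hb", "HbO2", "metHb")])
}

#' Resample a basis onto an analysis grid
#'
#' @param basis A [chromophore_basis()].
#' @param grid An [analysis_grid()].
#' @return The basis linearly interpolated onto the grid.
#' @export
resample_basis <- function(basis, grid) {
  chromophore_basis(
    basis_name(basis),
    Hb    = resample_spectrum(basis_component(basis, "Hb"), grid),
    HbO2  = resample_spectrum(basis_component(basis, "HbO2"), grid),
    metHb = resample_spectrum(basis_component(basis, "metHb"), grid)
  )
}

#' Combine components from different bases into a hybrid basis
#'
#' Builds the kind of "optimal" reference set in which the oxyhemoglobin
#' spectrum is taken from one compilation and the deoxyhemoglobin spectrum
#' from another, with methemoglobin from a designated provider. All three
#' source bases must share a wavelength grid.
#'
#' @param name Label for the hybrid.
#' @param HbO2_from,Hb_from,metHb_from Source [chromophore_basis()] objects.
#' @return A [chromophore_basis()].
#' @export
hybrid_basis <- function(name, HbO2_from, Hb_from, metHb_from = Hb_from) {
  chromophore_basis(
    name,
    Hb    = basis_component(Hb_from, "Hb"),
    HbO2  = basis_component(HbO2_from, "HbO2"),
    metHb = basis_component(metHb_from, "metHb")
  )
}

#' Apply a smooth shape perturbation to a basis
#'
#' Perturbs the Hb and HbO2 components by a smooth pseudo-random modulation
#' whose amplitude is `amplitude` times each component's 525-585 nm band
#' mean, emulating the few-percent shape disagreements between published
#' hemoglobin compilations. The metHb component is left untouched
#' (compilations largely agree there, and the comparison mechanism of
#' interest is the oxy/deoxy shape). Deterministic given `seed`; values are
#' clipped at zero to keep the basis physical.
#'
#' @param basis A [chromophore_basis()].
#' @param amplitude Relative perturbation amplitude (e.g. 0.05 for 5%).
#' @param seed Integer seed.
#' @param name Label for the perturbed basis.
#' @return A [chromophore_basis()].
#' @export
perturb_basis <- function(basis, amplitude = 0.05, seed = 1,
                          name = paste0(basis_name(basis), "_perturbed")) {
  stopifnot(amplitude >= 0)
  wl <- basis$wavelength_nm
  span <- diff(range(wl))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  modulate <- function(values) {
    # three random low-frequency sinusoids -> smooth, non-white shape change
    k <- stats::runif(3, 1, 4)
    phase <- stats::runif(3, 0, 2 * pi)
    w <- stats::rnorm(3)
    mod <- colSums(w * t(sapply(seq_len(3), function(i)
      sin(2 * pi * k[i] * (wl - wl[1]) / span + phase[i]))))
    mod <- mod / max(abs(mod))
    m <- mean(values[band_index(wl, 525, 585)])
    pmax(values + amplitude * m * mod, 0)
  }
  out <- chromophore_basis(
    name,
    Hb    = spectrum_tbl(wl, modulate(basis$Hb), "absorption_mm1"),
    HbO2  = spectrum_tbl(wl, modulate(basis$HbO2), "absorption_mm1"),
    metHb = basis_component(basis, "metHb")
  )
  out
}

# Save/restore the RNG state so seeded helpers do not disturb the caller's
# random stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read a basis declared in a YAML configuration
#'
#' The configuration maps each component to a two-column spectrum file (see
#' [read_spectrum()]) and optionally supplies an extinction-to-absorption
#' conversion:
#'
#' ```yaml
#' name: prahl
#' concentration_g_per_L: 150     # only needed for extinction inputs
#' molecular_weight_g_per_mol: 64500
#' components:
#'   Hb:    hb.tsv
#'   HbO2:  hbo2.tsv
#'   metHb: methb.tsv
#' ```
#'
#' Files in extinction units are converted; absorption files pass through.
#'
#' @param config A list as parsed from YAML, or a path to a YAML file.
#' @param dir Directory against which relative file paths are resolved.
#' @return A [chromophore_basis()] on the union grid of its files.
#' @export
read_basis_config <- function(config, dir = ".") {
  if (is.character(config)) {
    dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  comp <- config$components
  if (is.null(comp) || !all(c("Hb", "HbO2", "metHb") %in% names(comp))) {
    rlang::abort("Basis config must declare Hb, HbO2 and metHb components.",
                 class = "hb_error_config")
  }
  load_one <- function(path) {
    full <- if (file.exists(path)) path else file.path(dir, path)
    if (!file.exists(full)) {
      rlang::abort(sprintf("Component file '%s' not found.", path),
                   class = "hb_error_config")
    }
    spec <- read_spectrum(full)
    if (spectrum_unit(spec) == "extinction_Lmol1cm1") {
      spec <- convert_extinction_to_absorption(
        spec,
        config$concentration_g_per_L %||% 150,
        config$molecular_weight_g_per_mol %||% 64500
      )
    }
    spec
  }
  chromophore_basis(config$name %||% "unnamed",
                    Hb = load_one(comp$Hb),
                    HbO2 = load_one(comp$HbO2),
                    metHb = load_one(comp$metHb))
}
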