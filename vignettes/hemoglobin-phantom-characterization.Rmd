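---
title: "Characterizing liquid hemoglobin phantoms: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing liquid hemoglobin phantoms: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbphantom)
```

## The measurement problem

Optical oximeters report hemoglobin oxygen saturation (SO2) by decomposing
a measured spectrum into oxy- and deoxyhemoglobin contributions. Validating
such instruments needs a phantom whose SO2 is independently known and
controllable. Liquid phantoms made from whole blood, lysed blood or
dissolved freeze-dried hemoglobin fill that role, but each brings its own
confounders: intact erythrocytes scatter light, freeze-dried hemoglobin
contains a large methemoglobin (metHb) fraction, and added yeast (used to
consume dissolved oxygen and drive SO2 to zero) scatters strongly. On top
of that, the two tabulated hemoglobin extinction compilations in common use
disagree in spectral shape by up to about 10%, enough to bias SO2 by
percentage points depending on which one the analysis assumes.

`hbphantom` implements the laboratory workflow that untangles these
effects: collimated transmission at a series of precisely stepped optical
pathlengths gives the total attenuation spectrum with almost no light-transport
modeling; a five-parameter decomposition attributes it to the three
hemoglobin species plus a smooth scattering background; and an F-test on
residual magnitudes decides which reference compilation describes a given
preparation better.

## Stage 1: attenuation from multi-pathlength transmission

With collimated optics, transmitted intensity decays as
$I(\lambda, d) = I_0(\lambda)\, e^{-\mu_t(\lambda) d}$. For each
wavelength we regress $-\ln I(\lambda, d)$ on the pathlength $d$ by
ordinary least squares; the slope is $\mu_t(\lambda)$ (mm$^{-1}$) and the
intercept $-\ln I(\lambda, d_0)$ absorbs the incident intensity and any
pathlength-independent losses. Design choices:

* **Unweighted OLS.** The estimator is stated as a plain least-squares
  inversion; intensity-dependent weighting would be a refinement with no
  stated basis, and at the noise levels of a well-exposed spectrometer
  (≲1% multiplicative) it changes nothing material.
* **The zero-pathlength spectrum is a regression point, not a divisor.**
  Dividing by $I(\lambda, 0)$ would force the fit through that noisy
  point; fitting the intercept jointly uses it like any other observation.
* **Pathlength count is free.** Descriptions of this kind of setup give a
  25 μm step over 0–0.3 mm, which is 13 points, while sometimes quoting 15
  measurements; the estimator accepts any ≥ 2 distinct pathlengths, and
  the synthetic default uses the 13-point ladder `seq(0, 0.3, 0.025)`.
* **Degenerate wavelengths.** Non-positive intensities cannot enter the
  log and are excluded with a warning; a wavelength left with fewer than
  two usable points yields `NA` estimates rather than aborting the whole
  series, so one dead pixel or a saturated cell (see `mask_saturated()`)
  degrades only itself.

## Stage 2: chromophore + scattering decomposition

The attenuation model over the 490–620 nm fit band is

$$\mu_t(\lambda) = f_{Hb}\,\mu_{a,Hb}(\lambda)
 + f_{HbO_2}\,\mu_{a,HbO_2}(\lambda)
 + f_{metHb}\,\mu_{a,metHb}(\lambda)
 + \alpha\left(\frac{\lambda}{550\,\mathrm{nm}}\right)^{-\beta}
 + \varepsilon(\lambda).$$

The fractions $f_i$ scale reference absorption spectra tabulated for a
nominal concentration (whole blood: 150 g/L, molar mass 64 500 g/mol;
molar decadic extinction inputs are converted with
$\mu_a = \ln(10)\,\varepsilon\,C/MW$). The scattering term is a power law
pivoted at 550 nm, so $\alpha$ is the scattering coefficient there
(mm$^{-1}$) and $\beta$ its spectral slope; anisotropy is folded into
$\alpha$ under the assumption that it is spectrally flat over this narrow
band.

Numerical choices, all of which were open in the problem statement:

* **Box constraints.** $f_i \ge 0$, $\alpha \ge 0$, $\beta \in [0, 10]$.
  Negative chromophore fractions are unphysical, and reported results are
  fraction ratios, which constraints keep interpretable. Whether the
  original analyses constrained their solver is unknown; on all synthetic
  test instances the constrained optimum coincides with the unconstrained
  one whenever the latter is feasible.
* **Multi-start in $\beta$.** The model is nonconvex in $\beta$ only. We
  start at $\beta \in \{0.5, 1.5, 3\}$, initialize the four linear
  amplitudes at each start by a non-negative least-squares solve, refine
  all five parameters by Levenberg–Marquardt (`minpack.lm::nls.lm`), and
  keep the lowest final sum of squares.
* **Tolerances.** Relative SSE change $10^{-10}$, parameter step
  $10^{-8}$, 2000 evaluations per start — tight enough that on noiseless
  instances the solver agrees with an exhaustive variable-projection
  search ($\beta$ grid 0–10 in steps of 0.01, NNLS amplitudes at each
  grid point) to well below $10^{-8}$ in SSE and $10^{-6}$ in every
  parameter. That grid search is deliberately kept as an independent test
  oracle; it is never the production path.
* **Normalization happens at reporting time.** The fit runs on
  unnormalized $\mu_t$ (the model is linear in overall scale, so SO2 and
  all composition ratios are scale-invariant); spectra and residuals are
  divided by the 525–585 nm band mean of $\mu_t$ — the oxyhemoglobin
  "alpha band" — only for display and for the rms statistic, so samples
  of different concentration are comparable. Band membership is treated
  as a closed interval on grid points, since spectrometer bins land on
  band edges arbitrarily.
* **Absorption-only variant.** For reflectance-derived absorption spectra
  the scattering term is fixed to zero; the remaining problem is linear
  and is solved in one NNLS step (`fit_absorption()`).

The default analysis grid is 465 evenly spaced points on 490–620 nm
(≈ 0.28 nm), chosen to match the degrees of freedom N = 465 used by the
residual F-test below. Tabulated references (typically at 1 nm steps) are
placed on the grid by linear interpolation with no smoothing and no
extrapolation — smoothing would bias the very band shapes the comparison
is about; the interpolation scheme of the original analyses is unstated,
and linearity is the assumption-free choice.

## Stage 3: comparing reference compilations

If the residuals $\varepsilon(\lambda_i)$ were independent normals, the
squared rms residuals of two fits would each be $\chi^2(N)$-scaled and
their ratio $F(N, N)$-distributed. We put the larger squared rms in the
numerator, which makes the test two-sided at level $p$ with critical value
$F_{1-p/2}(N, N)$ — for $N = 465$ and $p = 0.01$ this is 1.27. Two
simplifications are inherited deliberately from the procedure being
reproduced rather than corrected: $N$ is not reduced for the five fitted
parameters, and spectral residuals are in truth autocorrelated across
neighboring wavelengths (that autocorrelation is exactly the "systematic
residual" signature a mismatched basis leaves, and the package's tests use
lag-1 autocorrelation against a white-noise null to detect it). The
F-verdict should therefore be read as a standardized effect-size summary,
not a calibrated type-I-error guarantee.

`optimal_basis()` implements the hybrid-reference idea: the compilation
that wins (lowest rms) on an oxygenated-dominant preparation donates its
HbO2 spectrum, the winner on a deoxygenated-dominant preparation donates
Hb, and metHb comes from a designated provider — in shipped configurations
always the Zijlstra-style source, mirroring the practice of taking metHb
from that compilation regardless of which oxy/deoxy set is in play.

## The synthetic phantom generator

No measured spectra of this kind are publicly deposited, so the package
ships a generator that plays the role of ground truth:

* `make_synthetic_basis()` builds three strictly positive reference
  spectra with the species' visible-band structure — HbO2 with the
  double peak near 542/577 nm, Hb with one broad band near 556 nm, metHb
  with an elevated 600–620 nm tail — at whole-blood amplitude scale
  (tens of mm$^{-1}$). A seed jitters centers, widths and amplitudes by a
  few percent so replicate studies do not share one fixed basis; the
  three components stay far from collinear (condition number ≪ $10^6$).
* `phantom_preset()` encodes the three preparations by their published
  composition signatures, chosen once as the generator's study
  conditions: whole-blood-like (scattering ≈ 7% of summed $\mu_t$,
  metHb < 1%), lysed-blood-like (no scattering, metHb < 1%), and
  freeze-dried-hemoglobin-like (lower concentration, ≈ 8% scattering,
  metHb 7% of total hemoglobin when oxygenated, 42% deoxygenated).
  Oxygenated presets sit at SO2 = 97% — full oxygenation is not reached
  in practice — and deoxygenated at 1%, with yeast scattering raised into
  the reported 25–51% range (30/40/25% for wb/lb/a0).
* **Noise model.** Intensities carry multiplicative lognormal noise
  (default σ = 0.5%), because the analysis lives in log space where this
  becomes additive Gaussian — the aggregate of shot and readout noise on
  a well-exposed detector. One integer seed drives every draw;
  identical seeds give bitwise-identical series.
* `deplete_oxygen()` reallocates $f_{HbO_2}$ to $f_{Hb}$ exactly
  conserving their sum (metHb untouched), emulating yeast deoxygenation.
  No quantitative yeast scattering spectrum is available, so the yeast
  contribution reuses the same single power-law form the fit model
  assumes, with its amplitude re-solved to hit a requested scattering
  fraction; this keeps the generator within the fitted model class, which
  is an acknowledged idealization.

What passing tests on these phantoms do show: the estimator chain is an
exact inverse of the forward model without noise, is unbiased at realistic
noise, and the basis-comparison machinery reliably detects few-percent
reference-shape errors. What they do not show: robustness to effects the
generator omits — hemoglobin sedimentation over time, oxygen diffusion at
the phantom surface, temperature drift, wavelength-dependent anisotropy,
spectrometer stray light, or dark-current structure (assumed corrected
upstream).

## Problem sizes and reproducibility

The shipped validation studies use the defaults above: the 465-point band,
13 pathlengths, 0.5% intensity noise, 100 replicates per preset for
recovery statistics, 20 noiseless instances for solver-vs-oracle
agreement, and 50 replicates for the 5% basis-discrimination study. On
the lysed-blood preset $\alpha = 0$, so $\beta$ is structurally
unidentifiable there and its recovery is assessed only on the scattering
presets. `scripts/acceptance.R` re-runs all of these from a single seed
and writes the resulting quantities as JSON.

## Known limitations

* Only the three hemoglobin species are modeled; carboxyhemoglobin,
  bilirubin and water are out of scope, as is estimating the anisotropy
  factor separately from $\alpha$.
* The F-test's independence assumption is idealized, as discussed above.
* Linear interpolation of references is a choice, not a known property of
  the original analyses; with ≈ 0.28 nm grid spacing against 1 nm source
  tables the interpolation error is far below the compilation-to-compilation
  shape differences under study.
* The generator's yeast scattering shares the fit model's functional
  form, so model-misfit from non-power-law scattering is not exercised.
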