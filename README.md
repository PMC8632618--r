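# hbphantom

Spectral characterization of liquid hemoglobin tissue phantoms from
collimated-transmission spectroscopy.

Liquid phantoms built from whole blood, lysed blood, or freeze-dried
ferrous-stabilized hemoglobin are the standard test bench for optical
oximeters, because their oxygen saturation can be varied on demand (e.g. by
adding oxygen-consuming yeast). Before such a phantom can serve as a
reference, its hemoglobin content has to be characterized: whole blood
carries residual erythrocyte scattering, freeze-dried hemoglobin carries a
substantial methemoglobin contamination, and the published hemoglobin
extinction compilations (Prahl's, Zijlstra et al.'s) disagree in shape by
up to ~10%, which propagates directly into SO2 estimates. `hbphantom`
implements the full characterization pipeline for users of such phantoms —
and, because measured spectra of this kind are rarely shared, a synthetic
phantom generator with known ground truth so every stage is verifiable.

## The model

From transmitted intensities I(λ, d) collected at several optical
pathlengths d, the total attenuation coefficient is estimated per
wavelength by inverse Beer–Lambert regression:

    d μt(λ) − ln I(λ, d₀) = −ln I(λ, d) + ε(λ, d)     (ordinary least squares in d)

The attenuation spectrum is then decomposed over the 490–620 nm band into
the three hemoglobin species plus power-law scattering:

    μt(λ) = f_Hb μa,Hb(λ) + f_HbO2 μa,HbO2(λ) + f_metHb μa,metHb(λ)
          + α (λ/550 nm)^(−β) + ε(λ)

by box-constrained nonlinear least squares (fractions and α non-negative,
β ∈ [0, 10], multi-start in β). Derived quantities:

* oxygen saturation `SO2 = 100·f_HbO2 / (f_Hb + f_HbO2)` (percent);
* scattering-corrected hemoglobin absorption
  `μa,Hb+HbO2(λ) = μt − f_metHb μa,metHb − μs(λ)`;
* scattering and methemoglobin contribution summaries.

Fits under alternative reference compilations are compared through the
ratio of squared rms normalized residuals, which is F(N, N)-distributed
under the white-residual assumption (N = number of band wavelengths; for
the default 465-point band the critical value at the 0.01 level is 1.27).
Tabulated molar extinction inputs are converted with
μa = ln(10)·ε·C/MW (C = 150 g/L, MW = 64 500 g/mol for whole blood).

## Worked example

```r
library(hbphantom)

grid  <- analysis_grid()                      # 465 points on 490-620 nm
basis <- make_synthetic_basis(grid, seed = 1) # ground-truth references
truth <- phantom_preset("wb", "oxy", grid, basis,
                        noise_sigma = 0.005, seed = 7)

series <- forward_transmission(truth)         # 13 pathlengths, 0-0.3 mm
mu_t   <- attenuation_spectrum(estimate_attenuation(series))
fit    <- fit_attenuation(mu_t, basis, grid)
fit
#> <hb_fit> attenuation decomposition, basis 'synthetic'
#>   f_Hb = 0.02975, f_HbO2 = 0.9699, f_metHb = 0.003744
#>   scattering: alpha = 0.8453 mm^-1 at 550 nm, beta = 1.12
#>   SO2 = 97.0%, rms normalized residual = 0.000701
```

The whole-blood-like preset is generated at SO2 = 97% with ~7% of its
attenuation due to erythrocyte scattering and under 1% methemoglobin; the
fit recovers all three from the noisy transmission series. Comparing the
generating basis against a 5% shape-perturbed alternative:

```r
alt    <- perturb_basis(basis, amplitude = 0.05, seed = 99)
report <- build_comparison(mu_t, list(synthetic = basis, perturbed = alt),
                           grid, label = "WB oxy")
report
#> <hb_comparison> 2 basis fit(s), 1 pairwise F-test(s), p = 0.01
#> # A tibble: 2 × 6
#>   preparation basis     so2 rms_norm_residual scattering_fraction methb_fraction
#>   <chr>       <chr>   <dbl>             <dbl>               <dbl>          <dbl>
#> 1 WB oxy      synthe…  97.0          0.000701              0.0712        0.00373
#> 2 WB oxy      pertur…  94.6          0.0218                0.0600        0.00579
#> # A tibble: 1 × 7
#>   preparation basis_a   basis_b   f_ratio   dof critical significant
#>   <chr>       <chr>     <chr>       <dbl> <int>    <dbl> <lgl>      
#> 1 WB oxy      synthetic perturbed    969.   465     1.27 TRUE
```

The wrong reference shapes shift the reported SO2 by over 2 percentage
points and leave a residual whose magnitude fails the F-test decisively —
the mechanism by which the pipeline identifies which compilation matches a
given preparation. `tidy()`, `glance()` and `autoplot()` methods give
tabular and graphical views of fits and reports; `run_sct_pipeline()` /
`run_absorption_pipeline()` run the same stages from delimited files and a
YAML config, and `inst/cli/hbphantom.R` wraps them for the shell.

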