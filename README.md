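# mrcytometry

Microstructural "MR cytometry" from time-dependent diffusion MRI, for
imaging scientists who combine oscillating-gradient (OGSE) and
pulsed-gradient (PGSE) spin-echo acquisitions to estimate cell-scale
tissue properties — and for anyone who needs a tested, self-contained
reference implementation of the models behind that analysis.

A multi-diffusion-time protocol (here: OGSE at 25 and 50 Hz plus a
conventional PGSE, 13 b-value volumes in total) samples water
displacement at length scales from a few micrometres up to the cell
diameter. Fitting the signals with a two-compartment model turns them
into per-voxel maps of:

- `v_in` — intracellular water volume fraction,
- `d` — mean cell diameter (µm),
- `D_ex` — extracellular diffusivity (µm²/ms),
- `k_in` — transcytolemmal water exchange rate (ms⁻¹),
- `rho = v_in / d × 100` — image-derived cellularity,

plus the per-sequence apparent diffusion coefficients
(`S = exp(-b·ADC)`). Three nested models are implemented:

- **IMPULSED** — impermeable spheres, exchange ignored:
  `S = v_in·exp(-b·ADC_r) + (1-v_in)·exp(-b·D_ex)`, with `ADC_r` the
  Gaussian-phase-distribution (GPD) restricted diffusivity of a sphere
  evaluated on the sequence's actual trapezoid-cosine waveform.
- **JOINT** — the Kärger two-site exchange solution on the PGSE volumes
  (`S = V1·exp(-b·D1*) + (1-V1)·exp(-b·D2*)`, eigen-solution of
  `A = -q²·diag(ADC_r, D_ex) + K`), IMPULSED on the OGSE volumes.
- **EXCHANGE** — a discretized integrator of the two-compartment
  magnetization system over the sampled gradient waveform (exact 2×2
  matrix exponential per step), valid for arbitrary waveforms.

Around the models sits the full analysis pipeline: a random-walk
Monte-Carlo oracle that validates every analytic expression, MP-PCA
(Marchenko–Pastur) denoising, IVIM removal by log-linear re-baselining,
SNR gating, seeded multi-start voxelwise fitting, a two-group synthetic
cohort generator with Rician noise, and the cohort statistics used to
discriminate tumour groups (Mann–Whitney, ROC/AUC with DeLong CIs and
paired tests, Youden operating points, prune-to-four penalized logistic
models, calibration and Brier scores, Dice, Pearson radio-pathology
correlation).

## Worked example

Simulate one voxel through the default protocol, fit it back, and look
at the protocol itself:

```r
library(mrcytometry)

scheme <- default_scheme()
scheme_table(scheme)
#> # A tibble: 13 × 6
#>    volume sequence  kind  b_s_mm2     b t_diff
#>     <int> <chr>     <chr>   <int> <dbl>  <dbl>
#>  1      1 OGSE_25Hz OGSE        0  0      10
#>  2      2 OGSE_25Hz OGSE      250  0.25   10
#>  3      3 OGSE_25Hz OGSE      500  0.5    10
#>  4      4 OGSE_25Hz OGSE      750  0.75   10
#>  5      5 OGSE_25Hz OGSE     1000  1      10
#>  6      6 OGSE_50Hz OGSE        0  0       5
#>  7      7 OGSE_50Hz OGSE      250  0.25    5
#>  8      8 OGSE_50Hz OGSE      500  0.5     5
#>  9      9 PGSE      PGSE        0  0      69.5
#> 10     10 PGSE      PGSE      250  0.25   69.5
#> 11     11 PGSE      PGSE      500  0.5    69.5
#> 12     12 PGSE      PGSE      750  0.75   69.5
#> 13     13 PGSE      PGSE     1000  1      69.5

# a mid-range tumour voxel: half the water intracellular, 14 um cells
p <- microstructure_params(v_in = 0.5, d = 14, D_ex = 1.8, k_in = 0.01)
signals <- simulate_signals(p, scheme, model = "JOINT")

fit <- fit_voxel(signals, scheme, fit_options("JOINT"))
fit[, c("v_in", "d", "D_ex", "k_in", "rho", "converged")]
#> # A tibble: 1 × 6
#>    v_in     d  D_ex    k_in   rho converged
#>   <dbl> <dbl> <dbl>   <dbl> <dbl> <lgl>
#> 1 0.500  14.0  1.80 0.0100   3.57 TRUE
```

The recovered parameters equal the simulated truth (noise-free signals
round-trip to better than 0.5% for all three models); `rho = 3.57`
means 0.5 volume fraction per 14 µm diameter, scaled by 100. The
restricted compartment is what makes the protocol informative — its
apparent diffusivity rises steeply as the diffusion time shortens:

```r
sapply(scheme$sequences, function(s) sphere_adc(d = 12, D_in = 1.56, s))
#> OGSE_25Hz OGSE_50Hz      PGSE
#> 0.4401949 0.8392626 0.0533942   # um^2/ms: ADC_PGSE < ADC_25Hz < ADC_50Hz
```

A full synthetic study — two groups with higher cellularity and lower
exchange in the poorly differentiated arm, SNR 25, MP-PCA, IVIM
removal, voxelwise fits, ROI means and the classification report — is
one call:

```r
res <- run_pipeline(default_group_specs(), scheme,
                    fit_opts = fit_options("IMPULSED"), master_seed = 1)
res$report          # publication-style table: AUC, 95% CI, Youden
                    # sensitivity/specificity/accuracy, calibration, Brier
autoplot(res$report)  # overlaid ROC curves
```

## Package layout

- `R/protocol.R`, `R/waveform.R` — sequences, timing, discretized
  waveforms, numerical b-values, feasibility.
- `R/gpd.R`, `R/models.R` — restricted-sphere GPD machinery and the
  IMPULSED / JOINT / EXCHANGE signal models.
- `src/mrc_core.cpp`, `R/mc.R` — the exchange propagator and the
  Monte-Carlo random-walk oracle.
- `R/preprocess.R` — MP-PCA, IVIM removal, ADC fits, SNR gating.
- `R/fitting.R` — multi-start bounded least squares, maps, ROI summaries.
- `R/cohort.R` — group specifications, Rician noise, phantom subjects
  and cohorts.
- `R/stats.R` — the cohort statistics and report builder.
- `R/pipeline.R`, `R/plots.R` — NIfTI I/O with volume sidecars, the
  end-to-end pipeline, ggplot2 `autoplot()`s and broom-style tidiers.
- `vignettes/mr-cytometry-methods.Rmd` — the models, assumptions,
  numerical choices and limitations in detail.
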