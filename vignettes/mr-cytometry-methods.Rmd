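---
title: "MR cytometry with combined OGSE and PGSE diffusion MRI: models, fitting and cohort statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR cytometry methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcytometry)
```

## The measurement

Time-dependent diffusion MRI probes tissue at controllable length scales.
A pulsed-gradient spin-echo (PGSE) sequence with gradient separation
$\Delta$ and duration $\delta$ has effective diffusion time
$t_{diff} = \Delta - \delta/3$; a cosine-modulated oscillating-gradient
(OGSE) sequence at frequency $f$ probes the much shorter
$t_{diff} \approx 1/(4f)$. Acquiring both in one session samples water
displacements from a few micrometres (OGSE at 50 Hz, $t_{diff}$ = 5 ms)
up to tens of micrometres (PGSE, $t_{diff}$ = 69.5 ms) — the scale of
tumour cells — and lets a biophysical model translate the signal decay
into cell-scale parameters: intracellular volume fraction $v_{in}$, mean
cell diameter $d$, extracellular diffusivity $D_{ex}$, transcytolemmal
water exchange rate $k_{in}$, and the derived cellularity
$\rho = v_{in}/d \times 100$.

The default `acquisition_scheme()` is the three-sequence rectal-imaging
protocol: OGSE at 25 Hz (1 cycle/lobe) and 50 Hz (2 cycles/lobe), both
with $\delta$ = 41.52 ms, plus PGSE with $\delta/\Delta$ = 13.52/74 ms;
b = 0–1000 s/mm² (0–500 for OGSE-50 Hz), 13 volumes in total, maximum
gradient 80 mT/m. Internally all times are ms, lengths µm, diffusivities
µm²/ms and b-values ms/µm², so that $b \cdot D$ and $k \cdot t$ are
order-one dimensionless numbers (1000 s/mm² = 1 ms/µm² exactly).

```{r}
scheme <- default_scheme()
scheme_table(scheme)
```

## Waveforms and the restricted-diffusion signal

`build_waveform()` realizes each sequence as a sampled effective gradient
trace (the refocusing pulse absorbed as a sign flip): trapezoidal PGSE
lobes, and trapezoid-cosine OGSE lobes — plateaus following the sign of
$\cos(2\pi n t/\delta)$ with linear slewing (default ramp 1 ms,
configurable; the scanner's slew limit corresponds to about 0.4 ms at
full amplitude). b-values are integrated numerically from
$q(t) = \gamma \int g\,dt'$, exactly for the piecewise-constant trace;
`required_gradient()` inverts the exact $b \propto g^2$ scaling and flags
amplitudes beyond the scanner limit. Sample-level vendor waveform shapes are not generally available, so b is
always computed from the constructed waveform rather than assumed.

The intracellular signal uses the Gaussian phase distribution (GPD)
approximation for an impermeable sphere of diameter $d$. Rather than
coding separate closed forms per sequence family, `sphere_adc()`
evaluates the GPD eigenmode series on the sequence's *actual* waveform:
the one-dimensional position autocorrelation in a reflecting sphere is
$\langle x(t)x(0)\rangle = \sum_k c_k e^{-\lambda_k t}$ with
$\lambda_k = \mu_k^2 D_{in}/R^2$, $c_k = 2R^2/(\mu_k^2(\mu_k^2-2))$ and
$\mu_k$ the roots of $j_1'$; the phase variance double integral is
reduced to an exact $O(NK)$ recursion over waveform samples. The
gradient amplitude cancels between phase variance and b-value, so
$ADC_r$ is amplitude-free. The series is truncated adaptively (relative
tail below $10^{-6}$, typically 6–10 modes). Two independent checks pin
this machinery: the van Gelderen closed form for rectangular-pulse PGSE
(agreement to ~$10^{-6}$ relative) and a brute-force random-walk
Monte-Carlo simulator (3% gate over $d \in \{8,12,16,20\}$ µm across all
three sequences).

## The three tissue models

All models share the two-compartment picture $S = v_{in} S_{in} +
(1-v_{in}) S_{ex}$ with $S_{ex} = e^{-b D_{ex}}$ and intracellular
intrinsic diffusivity fixed at $D_{in} = 1.56$ µm²/ms to stabilize
fitting.

* **IMPULSED** ignores exchange: $S_{in} = e^{-b\,ADC_r(d, D_{in})}$.
  Free parameters: $v_{in}, d, D_{ex}$.
* **JOINT** adds Kärger-type transcytolemmal exchange where it matters —
  on the long-diffusion-time PGSE volumes — while OGSE volumes retain the
  IMPULSED expressions. The PGSE signal is the eigen-solution of the
  $2\times2$ exchange-diffusion generator $A = -q^2\,\mathrm{diag}(ADC_r,
  D_{ex}) + K$ over $t_{diff}$, $q^2 = b/t_{diff}$, with mass-conserving
  $K = [[-k_{in}, k_{ex}],[k_{in}, -k_{ex}]]$ and detailed balance
  $k_{ex} = k_{in} v_{in}/(1-v_{in})$. This yields the biexponential
  $S = V_1 e^{-bD_1^*} + (1-V_1)e^{-bD_2^*}$ (ordering convention
  $D_1^* \le D_2^*$, exposed by `karger_decomposition()`). At
  $k_{in} = 0$ it reduces to IMPULSED at machine precision — the bridge
  identity between the methods.
* **EXCHANGE** integrates the same two-compartment system through the
  *sampled waveform*: $dM/dt = [-q(t)^2\,\mathrm{diag}(D_{in,app},
  D_{ex}) + K]\,M$, advanced with an exact closed-form $2\times2$ matrix
  exponential per piecewise-constant step (unconditionally stable; both
  eigenvalues are non-positive, so the evaluation is overflow-safe). The
  default intracellular apparent diffusivity is the sphere's GPD $ADC_r$
  matched to the sequence; the `d_in_app` hook substitutes any other
  expression (for example a dual-mode restricted/hindered intracellular
  model) without touching the integrator. In the narrow-pulse PGSE limit
  the integrator reproduces the Kärger closed form within 1%.

## The Monte-Carlo oracle

`mc_signal()` is the truth source for the analytic models: random
walkers with Gaussian steps, elastic reflection at sphere surfaces, and
membrane transit probability $p = P\sqrt{\pi\,\Delta t/D}$ (clipped),
which converges to permeability $P$ as $\Delta t \to 0$; the accumulated
phase $\phi = \gamma \sum g(t) x(t) \Delta t$ is linear in the gradient
amplitude, so one walk yields the signal at every b. Geometries: free
diffusion, a single (optionally permeable) sphere, and a periodic sphere
packing whose cell size realizes a target intracellular fraction. The
step length is kept below a tenth of the sphere diameter (enforced); the
oracle runs in the test suite at $\Delta t$ = 0.02 ms, where
$\sqrt{6 D \Delta t}$ = 0.43 µm against a minimum $d/10$ = 0.8 µm, and a
halving-$\Delta t$ check guards discretization. Walks are bitwise
reproducible for a fixed integer seed (a dedicated xoshiro256++ stream,
independent of R's RNG state).

## Preprocessing

The processing chain is fixed: (registration, out of scope) → MP-PCA
denoising → IVIM removal → per-sequence normalization → fitting.

* **MP-PCA** (`mppca_denoise()`): in each sliding patch (default
  5×5×3 voxels against 13 volumes, stride 1, overlapping reconstructions
  averaged) the voxel-by-volume matrix is eigendecomposed and components
  whose eigenvalues fit the Marchenko–Pastur bulk are removed; the bulk
  mean estimates the noise variance per patch.
* **IVIM removal** (`remove_ivim()`): perfusion inflates only the
  measured b = 0, so a log-linear fit over the diffusion window re-derives
  the baseline and all signals are renormalized by it. The window
  "$200 < b < 1000$" is read with an inclusive upper bound
  ($200 < b \le 1000$), keeping four points for the PGSE/OGSE-25 Hz grids
  and two for OGSE-50 Hz; both bounds are configurable. The operation is
  idempotent. For perfusion-free phantoms the stage is optional
  (`ivim = FALSE` normalizes by the measured baseline instead), because
  re-estimating a noiseless baseline from 2–4 noisy points only adds
  extrapolation variance.
* **ADC fitting** (`fit_adc()`): least-squares slope of $\log S$ over all
  b-values of a sequence, including the revised baseline. Negative fits
  are kept and flagged, never clipped, to preserve estimator properties
  downstream.
* **SNR gate** (`compute_snr()`): mean ROI intensity over mean background
  intensity with a pass threshold of 15. On magnitude images the
  background is the Rayleigh floor $\sigma\sqrt{\pi/2}$, so this ratio
  sits near $0.8\times$ the amplitude SNR — a property of the ratio rule
  itself, reproduced deliberately.

## Voxelwise fitting

`fit_voxel()` runs bounded Levenberg–Marquardt least squares over all 13
signals. Defaults: $v_{in} \in [0,1]$, $d \in [5,25]$ µm,
$D_{ex} \in [0.1,3]$ µm²/ms, $k_{in} \in [0,0.1]$ ms⁻¹ — physiologic
tumour scales chosen wide enough not to bind typical values; 8 seeded
Latin-grid starting points because the objective is multimodal in
$(v_{in}, d)$. All starts are scored and the best three receive full
optimizer runs; since the best-scoring start is always polished, the
returned objective never exceeds the objective at any tried start. The
per-voxel $ADC_r(d)$ is served from a cubic-spline table per sequence
(interpolation error below $10^{-5}$ relative), which makes the
17,200-voxel default cohort fit tractable on one core. Estimates pinned
at a bound are flagged; non-convergent voxels are flagged rows, not
errors. `roi_summary()` averages converged voxels, mirroring the
ROI-mean analysis convention, and reports the convergence fraction.

## The synthetic cohort: what it emulates, and what not

No patient data are distributed, so `generate_cohort()` provides the
test-bed: two groups with a realistic clinical split (37 poorly vs 49
well/moderately differentiated subjects), 200 ROI voxels per subject in
a 3-slice slab with a pure-noise border (so the SNR gate sees a
background), truth drawn i.i.d. per voxel from truncated normals, signals
forward-simulated through the full protocol (JOINT by default, so
exchange is present in the PGSE data), and Rician noise
$\sqrt{(S+n_1)^2+n_2^2}$ at $\sigma = 1/\mathrm{SNR}$ with SNR 25. The
group parameters are chosen for the expected directional contrast — not
as estimates of any measured clinical values: poor group $v_{in}$ 0.55 ± 0.07,
$D_{ex}$ 1.6 ± 0.25, $k_{in}$ 0.007 ± 0.003; well/moderate 0.40 ± 0.07,
1.9 ± 0.25, 0.012 ± 0.004; $d$ = 14 ± 2 µm in both. By construction the
truth cohort reproduces the qualitative pattern — $v_{in}$ and $\rho$
higher, $D_{ex}$, $k_{in}$ and all time-dependent ADCs lower in the poor
group, $d$ indistinguishable.

Two caveats matter when reading test results as statements about real
data. First, i.i.d. voxels with no between-subject heterogeneity make
ROI means extremely precise, so group separation at the cohort level is
far cleaner than any clinical AUC; the pipeline-level check therefore
compares the fitted classifier against the truth-derived oracle on the
same phantoms rather than against clinical numbers. Second, the absence
of spatial texture limits how much redundancy patch-based MP-PCA can
exploit; real tumours are smoother, and denoising performs better there.

### Identifiability at the default noise level

The voxelwise information budget is tight by design of the protocol: a
numerical Cramér–Rao analysis of the IMPULSED Jacobian at the default
tissue values gives an ideal-estimator floor of about 0.065–0.074 for
$v_{in}$ at raw $\sigma$ = 0.04 (SNR 25), against a pooled truth spread
of about 0.10. Voxelwise truth–estimate correlation for $v_{in}$ is
therefore bounded near 0.83 for any unbiased estimator without
denoising; with MP-PCA and exact normalization the package measures
$r \approx 0.83$ on the default cohort (the acceptance script reports
the value computed at run time). ROI means average this noise away, so
cohort-level discrimination is unaffected. Fitting the matched JOINT
model instead of IMPULSED removes the small exchange-induced bias but is
noisier voxelwise (four free parameters); the recovery measurement uses
IMPULSED for that reason.

## Cohort statistics

The statistics layer reproduces the study's analysis verbs on a cohort
table (one row per subject, `group` plus metric columns):

* `mann_whitney()` — exact enumeration of all label assignments for
  pooled n ≤ 12 (valid under ties), tie-corrected normal approximation
  otherwise.
* `auc_roc()` — rank-based AUC with half-credit ties; identical to
  $U/(n_1 n_2)$ by construction, an identity the tests assert to
  $10^{-12}$.
* `youden_operating_point()` — threshold maximizing sensitivity +
  specificity − 1; ties broken toward higher specificity (the more
  conservative operating point; no universal tie-break convention
  exists, so the choice is documented here).
* `delong_test()` / `auc_ci()` — paired DeLong comparison and 95% CIs via
  the placement-value covariance estimator (delegated to pROC,
  cross-checked against a subject-resampling bootstrap).
* `penalized_select()` — the prune-to-four rule: an L1 (optionally
  elastic-net) logistic path with the penalty increased from zero,
  variables dropped as coefficients hit zero until at most four remain,
  survivors refit unpenalized by maximum likelihood.
* `calibration_metrics()` — recalibration slope/intercept of the linear
  predictor plus the Brier score; `pearson_r()` with the r > 0.7
  "strong correlation" flag for radio-pathology comparisons;
  `dice()` and `pathology_cellularity()` for ROI agreement and
  nuclei-count densities.
* `cohort_report()` — the publication-style table (AUC, CI, Youden
  sensitivity/specificity/accuracy, calibration, Brier) for single-metric
  and combined panels, all computed in-sample on the same subjects so
  DeLong comparisons between models are valid. Raw p-values are reported
  without multiplicity correction, matching the source analysis
  convention.

## Numerical choices and degenerate inputs

* Eigen-coalescence in the Kärger solution ($s \to 0$) switches to a
  second-order series; all exponentials are of non-positive eigenvalues,
  so large exchange rates cannot overflow.
* $v_{in} = 1$ with $k_{in} > 0$ has no extracellular pool to balance:
  the public model functions raise a degenerate-balance error, while the
  fitting residual clamps $v_{in}$ to $1 - 10^{-6}$ so the optimizer may
  touch the bound without undefined behaviour.
* The waveform sampler requires at least 20 samples per OGSE period and
  `dt` ≤ 0.05 ms; the EXCHANGE integrator is exact per step, so its
  fitting-time grid (0.05 ms) is coarser than the b-value grid (0.01 ms)
  without loss (halving `dt` moves S by under $10^{-6}$).
* Problem sizes in the shipped tests: the Monte-Carlo equivalence grid
  runs 12 simulations of $10^5$ walkers at 0.02 ms steps; the cohort
  checks run the full 86-subject default cohort through the pipeline and
  a 16-subject balanced subset for voxelwise recovery. These sizes are
  the package's own trade-off between statistical resolution and a
  single-core desk run.

## Known limitations

* Orientation dispersion, non-spherical geometries, compartmental T2
  weighting and Rician-likelihood fitting are out of scope; fitting is
  least squares on magnitudes.
* The EXCHANGE intracellular default is the t_diff-matched GPD
  diffusivity — a documented placeholder behind the `d_in_app` hook, not
  a dual-mode intracellular model.
* Inter-sequence registration and nuclei segmentation are upstream of
  the package: stacks are assumed aligned, and pathology cellularity
  takes nuclei counts as input.
* The i.i.d. phantom makes cohort-level separation sharper than clinical
  reality; clinical AUCs cannot be reproduced from synthetic data and
  are not claimed.
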