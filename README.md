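# leupet

Kinetic modelling and heterogeneity analysis for L-[1-¹¹C]leucine PET.

## The problem

Dynamic L-[1-¹¹C]leucine PET measures the regional rate of cerebral protein
synthesis (rCPS) in vivo. In the homogeneous-tissue compartmental model the
macro parameters are the plasma-to-tissue transport rate constant *K*₁
(mL/g/min), the lumped efflux-plus-catabolism rate *k*₂+*k*₃ (1/min) and the
protein-incorporation rate *k*₄ (1/min), with

    rCPS = K₁ k₄ / (k₂+k₃) · Cp        λ = (k₂+k₃) / (k₂+k₃+k₄)

where *C*p is the unlabeled plasma leucine concentration (nmol/mL) and λ is
the fraction of the precursor pool fed from plasma. A voxel, however, is not
guaranteed to be kinetically uniform: partial-volume mixing of gray and
white matter (or any sub-voxel kinetic variation) makes the measured
time-activity curve (TAC) a weighted sum of subregion kinetics. Estimators
that assume uniformity — such as the basis function method (BFM), a grid
search over β = *k*₂+*k*₃+*k*₄ with linear least squares for the remaining
amplitudes — then overestimate rCPS. Spectral analysis with an iterative
filter (SAIF) instead fits a band-limited non-negative sum of
exponential-convolution components

    CT*(t) = θ₀ ∫₀ᵗ Cp* dτ + Σᵢ θᵢ ∫₀ᵗ Cp* e^{−βᵢ(t−τ)} dτ + Vb[Cb* − V_D Cc*] + V_D Cc*

and recovers K₁ = (θ₀+Σθᵢ)/(1−Vb), λ = Σθᵢ/(θ₀+Σθᵢ) and rCPS =
K₁(1−λ)/λ·Cp without assuming a single tissue. The number of equilibrating
components it reports is itself a per-voxel measure of kinetic
heterogeneity.

`leupet` implements both estimators, the forward models that generate
homogeneous and heterogeneous tissue curves, a frame-based Gaussian noise
model, the Monte Carlo machinery to compare the estimators (bias, RMSE,
outlier fraction, component-count classification), tracer-delay fitting, a
residual-resampling bootstrap classifier of voxel heterogeneity, and a 3D
brain-like phantom for studying how scanner resolution converts
partial-volume mixing into apparent kinetic heterogeneity. It is aimed at
researchers in quantitative PET who want a tested, fully synthetic-data
driven reimplementation of this analysis.

## Worked example

```r
library(leupet)
input    <- make_input_functions()          # synthetic 2-min infusion AIF
schedule <- default_frame_schedule()        # 42 frames over 90 min
dict     <- kinetic_dictionary(input, schedule)

truth <- homogeneous_params(K1 = 0.05, k2k3 = 0.1, k4 = 0.04, Vb = 0.05)
tac   <- homogeneous_tac(truth, input, schedule)
saif_fit(tac, dict)
#> SAIF fit: K1 = 0.05001 mL/g/min, lambda = 0.7143, rCPS = 2.4 nmol/g/min, Vb = 0.04999
#>   equilibrating components: 1
#>   WRSS = 9.364e-07
```

On kinetically uniform, noise-free data SAIF recovers the generating
parameters (true K₁ = 0.05, λ = 0.7143, rCPS = 2.4 nmol/g/min at
Cp = 120 nmol/mL) and reports one equilibrating component. Now make the
same tissue heterogeneous — two equal-weight subregions sharing λ and the
mean K₁, with a 5× turnover ratio — and fit both estimators:

```r
mix <- derive_heterogeneous(truth)
het <- heterogeneous_tac(mix, input, schedule)
bfm_fit(het, dict)
#> BFM fit: K1 = 0.04561 mL/g/min, lambda = 0.6675, rCPS = 2.726 nmol/g/min, Vb = 0.05427
#>   beta = 0.1565 1/min
#>   WRSS = 0.6918
saif_fit(het, dict)
#> SAIF fit: K1 = 0.05 mL/g/min, lambda = 0.7143, rCPS = 2.4 nmol/g/min, Vb = 0.05
#>   equilibrating components: 2
#>   WRSS = 1.353e-07
```

The mixture's true weighted rCPS is unchanged at 2.4 nmol/g/min; BFM,
locked to a single-tissue model, overestimates it by ~14%, while SAIF
detects both subregions and recovers it. `run_monte_carlo()` repeats this
comparison over a 19-set reference parameter library with 200 noise
realizations per set, `resolution_experiment()` runs the full phantom
study (voxelwise maps before and after 7.1-mm Gaussian smoothing,
heterogeneity fractions, regional summaries), and
`bootstrap_heterogeneity()` classifies single voxels.

A thin command-line wrapper for single fits, Monte Carlo reports and image
smoothing is installed at `inst/cli/leupet-cli.R`; small synthetic example
inputs (blood table, frame schedule, whole-brain TAC) live in
`inst/extdata/`.

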