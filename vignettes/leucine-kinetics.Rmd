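---
title: "Kinetic models, estimators and simulation design in leupet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models, estimators and simulation design in leupet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the compartmental models for L-[1-¹¹C]leucine PET, the two voxelwise
estimators it compares, the noise model and synthetic-data design, the
numerical choices that matter, and the limitations a user should know
before trusting a number.

## The tissue models

Leucine taken up from arterial plasma (rate constant $K_1$, mL/g/min)
either leaves the precursor pool again — efflux back to plasma plus the
first two catabolic steps, lumped as $k_2+k_3$ (1/min) — or is
incorporated into protein ($k_4$, 1/min). Labeled protein is assumed
stable over the 90-min study (no proteolysis of labeled product), so the
protein compartment acts as an irreversible trap. Two macro parameters
summarize the physiology:

$$\mathrm{rCPS} = \frac{K_1 k_4}{k_2+k_3} C_p, \qquad
  \lambda = \frac{k_2+k_3}{k_2+k_3+k_4},$$

with $C_p$ the unlabeled plasma leucine concentration (nmol/mL) and
$\lambda$ the fraction of the tissue precursor pool derived from plasma.
For a kinetically uniform tissue the measured total activity is

$$C_T^*(t) = (1-V_b)\frac{K_1 k_4}{\beta}\int_0^t C_p^*\,d\tau
 + (1-V_b)\frac{K_1 (k_2+k_3)}{\beta}\int_0^t C_p^* e^{-\beta(t-\tau)}\,d\tau
 + V_b\,[C_b^* - V_D C_c^*] + V_D C_c^*,$$

with $\beta = k_2+k_3+k_4$, blood volume fraction $V_b$, whole-blood
activity $C_b^*$, whole-blood ¹¹CO₂ activity $C_c^*$ and the fixed
blood:brain CO₂ distribution volume $V_D = 0.41$. A heterogeneous volume
is a weighted sum of $n$ such tissues sharing one blood term; collecting
terms gives the spectral form with trapping amplitude
$\theta_0 = (1-V_b)\sum_i w_i K_{1i} k_{4i}/\beta_i$ and equilibrating
amplitudes $\theta_i = (1-V_b) w_i K_{1i}(k_{2i}+k_{3i})/\beta_i$ at rates
$\beta_i$. The macro parameters follow from the spectrum alone
($K_1 = (\theta_0+\sum\theta_i)/(1-V_b)$, $\lambda =
\sum\theta_i/(\theta_0+\sum\theta_i)$, assuming a common $\lambda$ across
subregions), which is what makes spectral estimation attractive: the
subregion decomposition itself is not identifiable, the sums are.

The package never materializes the intermediate compartment
concentrations; the closed-form $C_T^*$ expressions are evaluated
directly (`homogeneous_tac()`, `heterogeneous_tac()`). In simulation mode
$C_c^* \equiv 0$ (brain ¹¹CO₂ contributes only 1–2% of measured activity
and is omitted); the full blood term is implemented and used whenever a
blood table supplies a ¹¹CO₂ curve.

## The estimators

**BFM** (`bfm_fit()`) assumes one tissue: for each of 100 candidate
$\beta$ values, logarithmically spaced on $[0.0037, 1.33]$ min⁻¹, it
solves weighted linear least squares for the three amplitudes (trapping,
equilibrating, blood) and keeps the $\beta$ with minimal weighted residual
sum of squares. Wherever the unconstrained solution has a negative
amplitude the grid point is refit under non-negativity constraints. With
only three columns the constrained optimum is found exactly by
enumerating the seven support subsets — each a closed-form solve on
precomputed cross-products — which makes the whole grid search a handful
of vectorized operations per voxel.

**SAIF** (`saif_fit()`) drops the single-tissue assumption: one weighted
non-negative least squares fit over the dictionary [trapping column,
one basis column per grid $\beta$ inside the bandpass $[0.02, 0.3]$
min⁻¹, blood column]. The bandpass separates the trap ($\beta = 0$) and
the blood component from genuine equilibrating tissue components and
suppresses noise-driven components outside the physiologic range. The
NNLS solve uses the Lawson–Hanson implementation in `pracma::lsqnonneg`
on square-root-weight-scaled rows; the test suite cross-checks it against
an exhaustive support-subset oracle on small problems (1e-8).

Both estimators return only non-negative macro parameters, and both flag
non-physiological fits ($K_1 > 1$ mL/g/min, $V_b > 1$, rCPS > 10
nmol/g/min) as outliers.

**Component counting.** Noise splits a single kinetic component across
neighboring grid points, so adjacent occupied grid points merge into one
equilibrating component; clusters separated by at least one empty grid
point count as distinct. A grid point is "occupied" only if its
contribution to the fitted curve exceeds 1e-9 of the data scale — the
NNLS solver can leave machine-precision dust on inactive columns, and
counting that dust would make noise-free classification meaningless. The
threshold sits many orders of magnitude below any noise-driven amplitude,
so it never affects classification statistics on noisy data.

**Degenerate fits.** If the total spectral mass is zero the fit is
flagged and all macro parameters are zero. If only the trap survives
($\sum\theta_i = 0$), $\lambda = 0$ is reported with the degenerate flag
and rCPS falls back to the net-uptake form $\theta_0/(1-V_b)\,C_p$,
since the $\lambda$-form divides by zero.

**Weights.** Frame weights are proportional to the inverse of the
modelled noise variance (below): $w_i \propto \Delta t_i
e^{-\gamma t_i} / \max(C_i, \text{floor})$, normalized to mean 1, with a
positivity floor of 1% of the TAC maximum so that near-zero or negative
observed frames keep finite weight. Weights are computed from the
observed TAC — on measured data the noise-free curve is unknown — and the
same rule is used in simulation for consistency.

**Delay fitting** (`fit_delay()`) scans candidate tracer delays (default
0–20 s in 1-s steps), shifts the input functions by each candidate, refits
the whole-brain TAC with SAIF and returns the delay with minimal WRSS,
ties broken toward the smaller delay.

**Bootstrap heterogeneity** (`bootstrap_heterogeneity()`) resamples
residuals normalized by the frame noise scale $s_i$, adds them back to the
fitted curve, refits with SAIF (default 50 replicates) and reports the
fraction of replicates with two or more equilibrating components; a voxel
is flagged heterogeneous at probability ≥ 0.80.

## Noise model and calibration

Frame noise is zero-mean Gaussian with variance

$$\mathrm{Var}[C_T^*(t_i)] = \alpha\, \frac{e^{\gamma t_i}\, C_T^*(t_i)}{\Delta t_i},$$

where $t_i$ is the frame mid-time, $\Delta t_i$ its duration and $\gamma =
\ln 2 / 20.34$ min⁻¹ the ¹¹C decay constant (configurable). In simulation
the variance is evaluated on the noise-free curve, where it is known. The
proportionality coefficient $\alpha$ is calibrated by
`calibrate_alpha()`: the "voxel" level sets the relative standard
deviation of the highest-activity frame of the mid-library TAC to 25%,
the "ROI" level to 5%. These are design choices — the original noise
scale factors were not published — and every $\alpha$-sensitive result
should be read as conditional on them. Note that under this variance
law the decay factor makes late frames far noisier than the peak frame:
at the voxel calibration the last 300-s frames carry a relative SD of
roughly 60%.

## Synthetic data

**Input functions** (`make_input_functions()`): labeled plasma leucine
rises linearly over a 2-min infusion to its peak, then decays as a
tri-exponential tail with half-times 1.5, 8 and 45 min and fractional
amplitudes 0.6/0.3/0.1 — a typical bolus-infusion arterial shape for this
tracer. Whole-blood activity is 0.8× plasma; whole-blood ¹¹CO₂ is zero in
simulation mode. The unlabeled plasma leucine concentration defaults to
120 nmol/mL, which puts rCPS for typical gray-matter kinetics in the
physiologic 1–2.5 nmol/g/min range. All of these are configurable; none
were fitted to any result.

**Reference library** (`reference_library()`): 19 parameter sets standing
in for inter-subject mean regional estimates, laid out by joint
deterministic interpolation across the physiologic ranges $K_1 \in
[0.025, 0.062]$ mL/g/min, $k_2+k_3 \in [0.054, 0.157]$ min⁻¹, $k_4 \in
[0.027, 0.053]$ min⁻¹ (endpoints included, $V_b = 0.05$ everywhere). The
true per-region values were not published; joint (rather than
independent) interpolation keeps the sets physiologically coherent —
slow-turnover sets resemble white matter, fast ones gray matter.

**Heterogeneous counterparts** (`derive_heterogeneous()`): two
equal-weight subregions sharing $\lambda$ and the mean $K_1$ (which
together preserve the weighted rCPS exactly), with a 5× ratio in
$\beta$ and a 25× ratio in $K_1(k_2+k_3)$ between the subregions. These
five constraints leave the absolute $\beta$ scale free; the package
anchors the weighted mean $\beta$ of the subregions at the homogeneous
$\beta$ (giving $\beta_a = 5\beta/3$, $\beta_b = \beta/3$), preserving
the mixture's mean turnover. A consequence worth knowing: for the
fastest library entries $\beta_a$ reaches 0.35 min⁻¹, just above the
SAIF band edge of 0.3 min⁻¹, so part of the fast subregion's mass is
represented at the band edge.

**Phantom** (`phantom_spec()`, `build_phantom()`): a 48×48×24 grid of
1.21×1.21×1.23 mm voxels with a gray-matter ellipsoidal shell (fastest
library entry) around a white-matter core (slowest entry). Every voxel is
kinetically homogeneous by construction; heterogeneity appears only after
`smooth_4d()` mixes classes inside border voxels. Noise is added per
voxel before smoothing, mirroring the acquisition order (reconstruction
noise precedes any resolution degradation).

## Numerical choices

* All internal time is minutes; file interfaces default to seconds (the
  protocol convention) and convert on load.
* Model curves are evaluated on a 1-s grid. The exponential convolution
  uses the piecewise-analytic recurrence (exact for piecewise-linear
  inputs), so large $\beta$ causes no stiffness; $\beta = 0$ is the
  running trapezoidal integral. Frame values are within-frame means of
  the fine-grid curve, because the variance model is defined on frame
  means. Halving the grid step changes frame values by well under 0.05%.
* The default 42-frame schedule (16×15 s, 4×30 s, 4×60 s, 4×150 s,
  14×300 s; 90 min) and the 100-point log $\beta$ grid with exact
  endpoints 0.0037 and 1.33 min⁻¹ are constructed, not stored.
* Monte Carlo runs are fully seeded: one seed fixes the noise matrices of
  all 19 sets and every fit, and reruns are bit-identical.
* Gaussian smoothing uses a separable truncated kernel
  ($\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$ per axis in voxel units, radius
  $4\sigma$, kernel normalized to unit sum), applied frame by frame via
  banded matrix products.

## Study sizes

The simulation study runs 19 sets × 200 realizations for each of three
scenario/noise combinations (homogeneous/voxel, heterogeneous/voxel,
heterogeneous/ROI — ROI noise is undefined for the homogeneous scenario,
since a region big enough for ROI-level noise is too big to be uniform).
The phantom experiment fits every brain voxel of the default 48×48×24
phantom twice (native and smoothed). Both complete in a few minutes on
one CPU; the acceptance script and test suite use exactly these sizes.

## What the synthetic data does and does not show

The generator reproduces the *structure* of a leucine PET study — frame
schedule, input-function shape, physiologic parameter ranges, the
two-subregion heterogeneity construction, frame-variance noise — but not
any particular measured dataset: the arterial curve is an idealized
shape, the 19 sets interpolate printed ranges rather than reproduce real
regions, and the phantom has two tissue classes with sharp borders rather
than anatomy. Passing tests therefore demonstrate correctness of the
algorithms and the direction and rough magnitude of the methodological
effects (model-mismatch bias, resolution-driven apparent heterogeneity),
not agreement with any subject's data.

Known limitations, found and kept honest rather than papered over:

* At the voxel-level noise calibration (25% relative SD at the peak
  frame), the slow subregion of a heterogeneous TAC is frequently
  absorbed by the trapping column, so SAIF under- rather than over-counts
  components; published behavior at "voxel noise" (over-splitting
  dominating, almost no false-homogeneous calls) corresponds to a
  substantially lower noise scale than this calibration produces. The
  component-classification statistics at voxel noise are therefore
  calibration-limited in this package.
* The sign of SAIF's small rCPS bias under heterogeneous/ROI conditions
  depends on the input-function shape and the band edge; its magnitude
  (a few percent) is the robust statement.
* SAIF is implemented as a single joint band-limited NNLS fit. The
  original method interleaves filtering and refitting; the joint fit
  realizes the same bandpass contract but is not a line-by-line
  reimplementation of that iteration.
* On noise-free data whose true $\beta$ falls between grid points, the
  residual quantization error is structured; bootstrap resampling of such
  residuals operates at that scale and can occasionally activate spurious
  tiny components. This matters only in the zero-noise limit.
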