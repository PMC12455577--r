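---
title: "Quantifying CEST-MRI Z-spectra: model, pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CEST-MRI Z-spectra: model, pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestz)
```

## The measurement and its model

Chemical exchange saturation transfer (CEST) MRI makes low-concentration
metabolites visible through the water signal: a long, frequency-selective
RF pulse saturates exchangeable solute protons, and chemical exchange
carries that saturation into the water pool, where it appears as a dip in
the water signal plotted against saturation offset — the Z-spectrum
$Z(\omega) = S(\omega)/S_0$, with $\omega$ in ppm relative to water at
0 ppm (positive = downfield).

`cestz` models a brain Z-spectrum as one minus a sum of five Lorentzian
dips,

$$Z(\omega) = 1 - \sum_{i=1}^{5} A_i
  \frac{(\Gamma_i/2)^2}{(\Gamma_i/2)^2 + (\omega - \delta_i)^2},$$

one pool each for direct water saturation ($\delta = 0$), the broad
semisolid magnetization-transfer (MT) background, creatine (CR, +2 ppm),
glutamate (GLU, +3 ppm) and the relayed nuclear Overhauser effect (NOE,
−3.5 ppm). $A_i$ is the peak depth in normalized-signal units,
$\Gamma_i$ the full width at half maximum in ppm. The model is fitted to
$Z$ directly (not to $1-Z$ or an asymmetry curve), with unweighted
residuals; this keeps the per-pool decomposition explicit and makes the
"CEST value" of a pool its fitted area under the curve.

Assumptions worth stating: pools add linearly (valid in the
weak-saturation regime; a Bloch–McConnell simulation below probes the
model error), the MT background is adequately described by a single broad
Lorentzian over ±5 ppm, and magnitude noise at the SNR of a normalized
spectrum is well approximated as Gaussian (a Rician option exists for
low-SNR work).

## Per-pool contrast: area under the Lorentzian

The per-pool AUC is analytic. Over the whole line
$\mathrm{AUC}_i = A_i\,\Gamma_i\,\pi/2$; over a window $[a, b]$,
$A_i\,(\Gamma_i/2)\,[\arctan\!\frac{b-\delta_i}{\Gamma_i/2} -
\arctan\!\frac{a-\delta_i}{\Gamma_i/2}]$. The full-line convention is the
default because no integration limits need to be chosen; both are exactly
linear in $A_i$, so group *contrasts* are invariant to the choice while
absolute values are not. `pool_auc()` implements both and the test suite
checks the closed forms against adaptive quadrature.

## Acquisition schedule and B0 correction

The default CEST schedule is 51 offsets from −5 to +5 ppm in 0.2 ppm
steps with 2 µT continuous-wave saturation for 1 s. B0 inhomogeneity
shifts each voxel's spectrum along the offset axis; it is mapped with a
separate WASSR acquisition (water saturation shift referencing): a
low-power (0.25 µT), narrow-range (±1 ppm, 0.02 ppm steps) scan in which
only the direct water line is visible. Its symmetric minimum marks the
voxel's true water frequency.

Per voxel, the shift is estimated by the maximum-symmetry center
frequency (MSCF) criterion: the center $c$ minimizing
$\sum_j [\hat Z(2c-\omega_j) - Z(\omega_j)]^2$ over offsets whose mirror
stays in range, via a coarse grid (0.01 ppm) plus parabolic refinement.
MSCF was preferred over a spline-minimum search because it uses the whole
line rather than the sampling of its minimum; a flat or unusable spectrum
is flagged `failed` rather than guessed, and optima on the search
boundary are flagged `edge`.

The CEST spectrum is then re-aligned by interpolating the acquired
spectrum at $\omega + \hat s$; end offsets whose source falls outside the
acquired range are dropped (never extrapolated) and simply ignored by the
fitter. The default interpolant is Floater–Hormann barycentric *rational*
interpolation (blending degree 3) rather than a cubic spline. This is a
deliberate numerical choice: the narrowest pool (CR, 0.5 ppm FWHM) is
sampled at only 2.5 points per FWHM, where the cubic-spline re-alignment
error reaches $1.15\times10^{-3}$ at half-grid-step shift phases —
spline theory bounds it near $(5/384)h^4\max|f''''| \approx
2.6\times10^{-3}$ — while the rational interpolant, which is exact for
the Lorentzian's rational form in the limit, stays below
$8\times10^{-4}$. Cubic and linear interpolation remain available via
the `interp` argument.

## The five-pool fit

Each voxel is fitted by bounded Levenberg–Marquardt (via
`minpack.lm::nls.lm`) with an analytic Jacobian, minimizing the residual
sum of squares over the 15 free parameters (amplitude, width, center per
pool). Defaults, surfaced in `fit_config()`:

| pool  | center (ppm) | A init | A bounds | Γ init (ppm) | Γ bounds | center slack |
|-------|----:|-----:|---------:|-----:|----------:|----:|
| water |  0   | 0.80 | [0.02, 1] | 1.4 | [0.3, 10]  | ±0.2 |
| MT    | −2.5 | 0.10 | [0, 0.5]  | 25  | [10, 100]  | ±2   |
| CR    | +2.0 | 0.02 | [0, 0.3]  | 0.5 | [0.2, 3]   | ±0.1 |
| GLU   | +3.0 | 0.03 | [0, 0.3]  | 1.0 | [0.2, 3]   | ±0.1 |
| NOE   | −3.5 | 0.05 | [0, 0.5]  | 3.0 | [0.5, 8]   | ±0.2 |

Three multistarts (amplitude initializations jittered by up to ±50%,
seeded) guard against local minima; ties resolve to the lowest residual,
then the fewest iterations. Convergence tolerances are $10^{-10}$ on
relative residual and parameter change with a 300-iteration cap; voxels
that fail every start propagate NaN into all maps and are excluded from
ROI means, with the exclusion fraction reported. Fits need at least 20
usable offsets.

On noiseless model spectra the fitter recovers amplitudes, widths and
centers to machine precision, and a brute-force grid search over the GLU
(amplitude, width) plane lands within one grid cell of its optimum. At a
realistic noise level the precision is bounded by information, not by the
optimizer: at $\sigma = 0.005$ per offset the Cramér–Rao bound for the
GLU amplitude in the 15-parameter fit is $\mathrm{sd}(A_{GLU}) \approx
0.005$, i.e. ~17% of the 0.03 amplitude, a median absolute relative
error floor near 11%. The test suite asserts the fitter sits within 1.5×
that floor and that errors shrink monotonically with noise — useful
context for single-voxel GLU maps, and the reason region averaging (over
voxels or spectra) is what makes group comparisons well powered.

## From maps to group statistics

ROI values are the mean AUC over a region's converged voxels, for the
four labeled regions (cortex, hippocampus, piriform cortex, thalamus)
plus whole brain, always derived as the union of labeled voxels. Group
summaries are mean ± SEM (sd/√n after exclusions); inference is ordinary
one-way ANOVA plus two-tailed pooled-variance (Student) t-tests for the
configured pairs, with p < 0.05 flagged `*` and 0.05 < p < 0.1 flagged
`#`. Pooled variance was chosen over Welch for consistency with the
ordinary ANOVA ($F = t^2$ for two groups, an identity the tests verify
to $10^{-12}$); Welch and Holm adjustment are available but off by
default, matching common practice in small preclinical studies.

Outliers are excluded per (group, region, pool) before testing, using
Tukey fences at $k = 1.5$ ("150% of the IQR") with quartiles by linear
interpolation of order statistics (`quantile` type 7). The convention is
configurable because it is decisive at n = 4. Two findings from the
package's own null-phantom calibration deserve emphasis:

* With type-7 quartiles, the fence flags a value in about **21% of
  perfectly normal n = 4 groups**, and the end-to-end false-positive
  rate of the pipeline roughly doubles, from 0.056 to ~0.11 at
  $\alpha = 0.05$ (500 null studies; `simulate_null_rejection()`
  reports both numbers). Automatic per-cell fence exclusion at n = 4 is
  therefore *anti-conservative*, and significance flags obtained with it
  should be read accordingly.
* The obvious alternative — Tukey's original hinges (type 2) — restores
  nominal calibration only because its n = 4 fences are algebraically
  inert: an upper extreme inflates Q3 itself, making exclusion of a
  maximum impossible. A convention under which a single subject *can* be
  excluded at n = 4 is necessarily one that also inflates the type-I
  rate.

The IQR = 0 edge case (identical values) skips exclusion with a warning;
groups below 3 values are never pruned. Whole-animal (global) exclusion
is available as an alternative to per-cell exclusion.

## The synthetic phantom

Because no acquired data ship with the package, every stage is validated
against an in-silico study generator with known ground truth
(`phantom_config()` / `generate_phantom_study()`). Its defaults define
the study conditions:

* 4 groups (vehicle, ART, nicotine, cotreat) × 4 subjects, one 64×64
  slice (tests and Monte-Carlo calibration use 16×16), geometric ROI
  layout with the four named regions inside an elliptical brain;
* per-region pools = the baseline table scaled by (group, region, pool)
  amplitude factors — by default thalamic GLU × 0.7 in all three
  treatment groups and hippocampal NOE × 1.3 under co-treatment,
  mirroring the kind of region-specific effects the pipeline is meant to
  detect;
* a smooth low-order per-subject B0 field (default ±0.1 ppm, a typical
  post-shim residual at high field), matching WASSR stacks, constant S0
  reference, and Gaussian noise of sd 0.005 on the normalized signal
  (a moderately conservative preclinical SNR; Rician optional);
* one root seed expanded deterministically into per-subject seeds, so
  identical configurations are bit-identical and ground truth is
  invariant to the noise seed.

What the generator does *not* emulate: readout and k-space effects,
motion, partial-volume anatomy, spatially varying S0 or B1, and
non-Lorentzian MT lineshapes. Passing tests therefore demonstrate
correctness of the estimation machinery under the generative model, not
robustness to every physical confound of real data.

As a model-independent oracle, `simulate_bloch_mcconnell()` integrates
the coupled Bloch–McConnell equations (matrix-exponential propagation of
all pools under continuous-wave saturation from thermal equilibrium) for
a documented physics table at 7 T — a typical preclinical field strength,
needed to convert ppm to rad/s. Fitting the five-pool model to that
physics-generated spectrum recovers the narrow-pool centers (water, CR,
GLU, NOE) within 0.1 ppm; the broad MT pool's center is intrinsically
ill-determined under a >100 ppm-wide line and is not held to that bar.

## Voxelwise and ROI-mean analysis modes

`analyze_study()` offers two routes to the ROI value table. The default
`voxelwise` mode builds a per-voxel field map, fits every masked voxel
and averages the per-pool AUC maps over each region — the mode matching
per-voxel contrast heatmaps. The `roi_mean` mode averages the WASSR and
CEST spectra over each region first and fits one spectrum per region.
The two agree exactly on noiseless, homogeneous-field phantoms (a suite
invariant); under B0 heterogeneity the ROI-mean spectrum is a mixture of
shifted lines, which biases absolute amplitudes slightly upward while
leaving the group *comparison* machinery identical. The package's
Monte-Carlo calibration harnesses (`simulate_null_rejection()`, 500
studies; `simulate_effect_direction()`, 100 studies; both at 16×16)
use `roi_mean`, which makes a 500-study calibration a ~4-minute
computation; single studies default to voxelwise.

## Numerical and degenerate-input choices

* Offsets must be strictly increasing; descending tables are reordered
  with their volumes (`sort_offsets()`); duplicate offsets are errors.
* Masked-out voxels never influence any output (a property test poisons
  them with garbage and asserts bit-identical results).
* S0 ≤ 0 voxels are dropped from the mask with a count; a stack without
  a reference must be explicitly declared pre-normalized.
* MSCF needs ≥ 7 points and ≥ 5 valid mirror pairs per candidate;
  anything less is `failed`, and > 50% failures abort with a hint that
  the WASSR schedule does not span the field.
* Zero pooled variance in a t-test yields p = 1 for equal means and
  p = 0 with a warning otherwise; ANOVA with zero between- and
  within-variance yields F = 0, p = 1.
* All randomness flows from explicit seeds; identical config + seed
  gives bitwise-identical statistics tables.

## Known limitations

Single-slice 2-D geometry only; no B1 correction (low-power WASSR and
moderate saturation power make it second-order here, and it would need a
B1 map the data model does not carry); no registration between subjects
(the phantom shares one grid); the MT pool is a Lorentzian, not a
super-Lorentzian, so very broad MT backgrounds can leak into neighboring
pools; and the fence-rule calibration caveat above applies to any
statistics consumer, not just the built-in one.
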