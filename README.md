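# cestz

Quantitative CEST-MRI Z-spectrum analysis for preclinical brain studies:
WASSR-based B0 field mapping, five-pool Lorentzian decomposition,
per-pool AUC contrast maps, and ROI group statistics — plus a synthetic
phantom generator with known ground truth so the whole pipeline is
testable without acquired data.

## The problem

Chemical exchange saturation transfer (CEST) MRI detects low-concentration
metabolites — glutamate, creatine, mobile macromolecules — through the
water signal: frequency-selective saturation of exchangeable protons is
transferred to water and appears as dips in the Z-spectrum
`Z(ω) = S(ω)/S0` versus saturation offset ω (ppm, water at 0). Turning
raw saturation images into defensible group comparisons requires a chain
of steps, each easy to get subtly wrong: per-voxel B0 correction (each
voxel's spectrum is shifted by the local field), decomposition of the
spectrum into overlapping resonances, a contrast definition, ROI
aggregation, and small-n group statistics. `cestz` implements that chain
for the five-pool brain model

```
Z(ω) = 1 − Σᵢ Aᵢ (Γᵢ/2)² / ((Γᵢ/2)² + (ω − δᵢ)²)
```

with pools water (0 ppm), MT (broad, −2.5 ppm), CR (+2 ppm), GLU
(+3 ppm) and NOE (−3.5 ppm); the per-pool "CEST value" is the area under
its Lorentzian, `AUC = A·Γ·π/2`. B0 shifts are estimated from a WASSR
scan by the maximum-symmetry criterion; fitting is bounded
Levenberg–Marquardt with analytic Jacobians; statistics are mean ± SEM,
Tukey-fence outlier exclusion, one-way ANOVA and pairwise two-tailed
t-tests with `*` (p < 0.05) and `#` (0.05 < p < 0.1) flags.

It is aimed at imaging scientists who want a scripted, reproducible,
validated alternative to one-off fitting code: every stage is exercised
against generated data with known truth, a Bloch–McConnell physics
simulator provides a model-independent oracle, and Monte-Carlo harnesses
measure the statistical calibration of the full pipeline.

## Worked example

Simulate a 16-subject study (4 groups × 4, with thalamic GLU reduced to
0.7× in the treated groups and noise on every spectrum), then run the
full pipeline — field maps, voxelwise five-pool fits, AUC maps, ROI
statistics:

```r
library(cestz)

cfg <- phantom_config(grid_shape = c(16L, 16L),
                      roi_layout = default_roi_layout(c(16L, 16L)),
                      seed = 42L)
res <- run_phantom_study(cfg, mode = "voxelwise")

subset(res$stats$summary, region == "thalamus" & pool == "GLU")
#>    region pool    group n   mean     sem
#>  thalamus  GLU  vehicle 4 0.0494 0.00263
#>  thalamus  GLU      ART 4 0.0399 0.00392
#>  thalamus  GLU nicotine 4 0.0360 0.00380
#>  thalamus  GLU  cotreat 4 0.0385 0.00607

subset(res$stats$tests, region == "thalamus" & pool == "GLU",
       select = c(group1, group2, t, p, flag))
#>    group1   group2      t      p flag
#>       ART  vehicle -2.011 0.0911    #
#>  nicotine  vehicle -2.912 0.0269    *
#>   cotreat  vehicle -1.657 0.1485
#>   cotreat      ART -0.202 0.8464
#>   cotreat nicotine  0.350 0.7385
```

The group means are thalamic GLU AUC values (ppm · normalized signal):
the vehicle mean sits near the ground-truth `0.03 × 1.0 × π/2 ≈ 0.047`
and the treated groups near `0.7×` of it; with only four subjects per
group and realistic noise, some true effects land as trends (`#`) or
miss the 0.05 bar in any single simulated study — which is exactly what
the Monte-Carlo harnesses below quantify. `res$report$pct_nonconverged`
records the fraction of voxels excluded from the maps (1.3% here).

The same pipeline runs from the shell on studies written to disk:

```sh
Rscript inst/cli/cest-zspec.R simulate --config cfg.yaml --out study/
Rscript inst/cli/cest-zspec.R analyze --study study/ --out results/
```

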