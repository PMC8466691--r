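# muscledti

Quantification of skeletal-muscle diffusion tensor imaging (mDTI) with the
two segmentation strategies used in clinical muscle studies, and the
statistics needed to compare them.

Muscle DTI is an emerging biomarker for neuromuscular disease: water
diffusion in muscle is modelled per voxel as a symmetric tensor
*D*, estimated from diffusion-weighted volumes via
S_i = S_0 · exp(−b_i · g_iᵀ D g_i), and summarised by fractional anisotropy
(FA), mean diffusivity (MD), axial diffusivity (λ₁) and radial diffusivity
(RD). Because these metrics differ between muscles, muscles must be
separated first — and *how* they are separated changes the numbers:

* **MSB** — manual-segmentation-based analysis: masks are smoothed, eroded
  by one voxel, resampled to diffusion space, and each in-mask voxel
  contributes exactly once to the muscle mean.
* **VBT** — volume-based tractography: deterministic streamlines (max
  angle 15°, step 1.5 mm, FA 0.1–0.6) are tracked inside each muscle and
  metrics are sampled along the tracts, weighting each voxel by its
  visitation count. VBT additionally yields tract properties: tract density
  (TD), mean tract length (MTL), volume (Vol) and the mean fiber angle
  against the craniocaudal axis (a pennation estimate).

The package provides, for seven calf muscles:

* NIfTI / FSL-gradient / TCK / CSV / JSON I/O with strict grid bookkeeping;
* per-voxel weighted-least-squares tensor estimation with
  iterative-reweighting outlier rejection (Geman–McClure IRLS, κ = 6
  flagging, WLS refit) and scalar maps (FA, MD, λ₁, RD, SNR);
* mask post-processing, nearest-neighbour label resampling, MSB extraction
  and fat-fraction summaries;
* streamline tractography with visitation-weighted sampling and tract
  properties;
* the full inter-rater reliability battery: CV, paired *t*, Pearson *r*,
  ICC (two-way single-measures, agreement and consistency forms),
  Cronbach's α, Bland–Altman limits of agreement;
* a synthetic pennate-muscle phantom (17 directions at b = 400 s/mm²,
  3 × b = 0, 3 × 3 × 6 mm³ voxels, Rician noise at SNR 59, fat
  infiltration, simulated two-rater segmentations) that carries its ground
  truth, so every pipeline stage can be validated without scanner data.

See the methods vignette (`vignettes/muscle-dti-reliability.Rmd`) for the
models, parameter defaults and design rationale.

## Worked example

Simulate one phantom subject, fit the tensor field, and compare the two
extraction strategies against the generator's ground truth:

```r
library(muscledti)

spec <- phantom_spec(seed = 7)        # healthy cohort, SNR 59
sim  <- simulate_dwi(spec)
fit  <- fit_dti(sim$dwi, sim$scheme, mask = sim$labels$labels > 0)
print(fit)
#> <dti_fit> 78048 voxel(s) fitted (robust), 0 fallback, 2039 measurement outliers total
#> <image_grid> 64 x 64 x 40 voxels, 3 x 3 x 6 mm

maps <- eigen_maps(fit)
msb  <- extract_msb(maps, smooth_and_erode(sim$labels))
vbt  <- vbt_report(fit, sim$labels)
head(vbt[, c("muscle", "fa", "md", "td", "mtl", "mean_angle")], 3)
#>                    muscle     fa    md    td   mtl mean_angle
#> 1      extensor_digitorum 0.2033 1.702 18.50 152.5      10.26
#> 2 gastrocnemius_lateralis 0.2142 1.403 18.49 146.7      12.13
#> 3  gastrocnemius_medialis 0.2715 1.439 18.45 128.7      17.03

max(abs(msb$md / sim$truth$muscles$md_eff - 1))   # MD recovery error
#> [1] 0.00038
max(abs(vbt$mean_angle - spec$muscles$pennation)) # pennation error, degrees
#> [1] 0.26
```

FA and MD sit in the range expected of healthy calf muscle (FA ≈ 0.2,
MD ≈ 1.4–1.7 × 10⁻³ mm²/s, varying between muscles as a real cohort's do),
`mean_angle` recovers each muscle's configured pennation (8–20°) to a
fraction of a degree, and both strategies recover the per-muscle mean
diffusivity to ~0.1% at the protocol SNR.

A full two-rater experiment over several subjects, with reliability
reports written alongside the tables:

```r
res <- run_pipeline(list(n_subjects = 4, seed = 1), out_dir = "out")
res$reliability$msb$md
#> Reliability report for 'md' (n = 28 pairs)
#>   CV: 0.072 / 0.072   ICC(A,1): 1.000   ICC(C,1): 1.000   alpha: 1.000
#>   Pearson r: 1.000   paired t: 0.725 (p = 0.475)
#> Bland-Altman (n = 28): mean diff 2.13e-05, SD 0.0001555, LoA [-0.0002835, 0.0003261]
```

The two simulated raters disagree only through boundary jitter, so the
pooled inter-rater ICC is essentially 1 and the Bland–Altman mean
difference is indistinguishable from zero — the agreement pattern expected
of a low-rater-dependency protocol. The inter-subject CV (0.07 for MD)
matches the spread configured into the cohort simulation.

The same stages are available from the shell through the bundled CLI
(`system.file("cli", "muscledti", package = "muscledti")`) with subcommands
`simulate`, `fit-tensor`, `extract-msb`, `track-vbt`, `reliability` and
`run-all`.

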