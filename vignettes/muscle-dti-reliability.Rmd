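---
title: "Muscle DTI quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle DTI quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(muscledti)
```

# The problem

Muscle diffusion tensor imaging (mDTI) characterises skeletal-muscle
microstructure through the per-voxel diffusion tensor of water. Because
diffusion metrics differ between individual muscles, any quantitative use
requires separating muscles first, and two segmentation strategies dominate
clinical muscle studies:

* **MSB** (manual-segmentation-based analysis): delineated muscle masks are
  superimposed on the scalar maps and each in-mask voxel contributes exactly
  once to the muscle mean.
* **VBT** (volume-based tractography): deterministic streamlines are tracked
  inside each muscle volume and metrics are sampled along the tracts, so a
  voxel contributes once per tract visitation. VBT additionally yields tract
  properties — tract density (TD), mean tract length (MTL), muscle volume
  (Vol) and the mean fiber angle against the craniocaudal axis, a tract-level
  pennation estimate.

The two weighting schemes are the central methodological contrast: they agree
on homogeneous tissue and diverge systematically when muscles contain
low-quality or partial-volume regions that tracking avoids but voxel
averaging includes. This package implements both strategies end to end, the
full inter-rater reliability battery used to compare them, and a synthetic
pennate-muscle phantom that provides ground truth for every stage.

# Signal model and tensor estimation

Each voxel follows the mono-exponential tensor model

$$S_i = S_0 \, e^{-b_i\, \mathbf{g}_i^{\mathsf T} D\, \mathbf{g}_i},$$

with $b$ in s/mm² and the symmetric tensor $D$ carried in units of
$10^{-3}$ mm²/s throughout (the scale on which muscle diffusivities are
conventionally reported). The emulated acquisition uses 17 gradient
directions at $b = 400$ s/mm² plus three $b = 0$ volumes on a
$3 \times 3 \times 6$ mm³ grid.

`fit_tensor_wls()` fits the log-linearised model: ordinary least squares
initialisation, then weighted least squares with weights equal to the squared
predicted signals (the first-order correct weighting for log-transformed
magnitude data), iterated to a relative parameter change below $10^{-6}$
(at most 20 iterations).

`fit_tensor_robust()` adds outlier rejection in three stages: a
Geman–McClure iteratively-reweighted fit, residual-based flagging at
$\kappa = 6$ robust standard deviations, and a final plain WLS refit on the
retained measurements. Three numerical choices deserve explanation, because
the acquisition leaves only 13 residual degrees of freedom (20 measurements,
7 parameters):

* Residuals are judged on the **signal scale** (log-residual times predicted
  signal): log-domain residuals have different variances at $b = 0$ and
  $b = 400$, so a MAD over raw log residuals systematically mis-scales the
  threshold.
* The robust scale is the dof-corrected MAD
  ($1.4826\,\mathrm{MAD} \cdot \sqrt{m/(m-p)}$) of the *initial* WLS fit and
  is **held fixed during the IRLS**. Re-estimating the scale from the
  redescending fit's own residuals collapses it — with few residual degrees
  of freedom the Geman–McClure fit absorbs the majority of the points and its
  residual MAD underestimates the noise several-fold, flagging
  of order 15% of perfectly clean measurements. For the flagging step the
  scale is re-estimated once from the converged robust fit, so that a gross
  outlier cannot inflate the threshold that should catch it.
* The Geman–McClure weight uses a tuning constant of 3 robust SDs. At this
  design size that leaves inliers essentially unweighted (false-flag rate
  about 0.15% per measurement on clean data in our simulations) while a
  3-fold corrupted measurement is still annihilated and recovered exactly.

If exclusion would leave fewer than seven measurements or no $b = 0$
baseline, the voxel falls back to the plain WLS estimate and is flagged; a
MAD-based threshold can never flag a majority, so in practice the fallback
triggers through the $b = 0$ rule. Voxels with negative eigenvalues are
kept in the maps but flagged, and all flagged voxels are excluded from
muscle means — silent clamping would bias them.

Scalar maps follow the standard definitions: eigenvalues sorted descending,
$\mathrm{MD} = \bar\lambda$, $\mathrm{RD} = (\lambda_2 + \lambda_3)/2$,
$\mathrm{FA} = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i - \bar\lambda)^2 / \sum_i
\lambda_i^2}$ (0 for an all-zero tensor). SNR is the mean $b=0$ signal over
the local noise sigma, undefined (not infinite) where sigma is zero.

# Mask post-processing and MSB extraction

Masks are smoothed by per-label binary closing and eroded by one voxel
(default) with a 6-connected 3-D structuring element before metrics are
extracted — the standard guard against partial-volume contamination at
muscle boundaries. The closing step never expands a label into a voxel owned
by another label. Both the connectivity (6 or 26) and the erosion depth are
exposed because neither is universal across sites. Label maps are resampled
to the diffusion grid by nearest-neighbour assignment of voxel centres
through both affines; labels are categorical and are never interpolated.

Fat fractions are averaged per muscle on the *un-eroded* masks, and the
whole-calf value is the unweighted mean of the per-muscle means — muscles
count equally regardless of size, which is the convention in the clinical
literature this package follows.

# Tractography

`track_muscle()` seeds every in-mask voxel centre whose FA lies within the
tracking range and integrates bidirectionally along the principal
eigenvector (Euler steps, per-step sign alignment to the incoming
direction). Defaults follow the published muscle protocol: maximum turning
angle 15° per step, step 1.5 mm, FA range 0.1–0.6; streamlines shorter than
10 mm are discarded and integration is capped at 2000 steps per direction.
Seeding density, integrator, interpolation and the length cap are not fixed
by any protocol and are therefore configuration knobs recorded in every
report.

The direction field is obtained by trilinear interpolation of the six tensor
components restricted to in-mask voxels (out-of-mask and non-finite
neighbours carry zero weight, with the weights renormalised), followed by
eigen-decomposition at the interpolated point. Masked interpolation keeps a
homogeneous muscle exactly homogeneous up to its boundary, which makes the
analytic geometry checks sharp; non-finite voxels act as barriers.

`tract_sample()` samples maps at the **nearest voxel** of every streamline
point, so "visitation counting" has a literal voxel-count meaning: the
muscle metric is the mean over all points of all streamlines, and
`tract_sample()` provably equals the MSB mean when every voxel is visited
exactly once. `tract_properties()` reports Vol as the volume of the
un-eroded mask (the segmentation is the defined volume; a tract-envelope
volume would conflate tracking quality with anatomy), TD as streamlines per
cm³ of that volume, MTL as mean arc length, and the mean angle against the
+z slice-stack axis — the craniocaudal direction. The reference axis is an
assumption (protocols rarely state it) and is logged in the reports.

# Reliability statistics

All statistics operate on paired per-muscle tables aligned on (subject,
muscle): coefficient of variation (sample SD over mean, the n−1 convention
everywhere), two-sided paired *t*, Pearson *r*, Cronbach's α, Bland–Altman
limits of agreement ($\bar d \pm 1.96\,s_d$), and the intraclass correlation
from the two-way ANOVA mean squares. Two ICC conventions matter:

* **ICC(A,1)** — two-way, single measures, absolute agreement — is the
  default, because the question "do two raters produce the same value" is
  about absolute agreement. This is the single most consequential ambiguity
  in reproducing published reliability numbers (statistical packages offer
  half a dozen ICC forms and papers rarely name one), so both the agreement
  and consistency forms are always reported side by side and the model is
  named in every output.
* ICC(A,1) ≤ ICC(C,1) whenever the rater variance component is
  non-negative; when the rater mean square falls below the error mean square
  the inequality can reverse slightly. That regime is sampling noise around
  a zero rater effect, not a meaningful disagreement.

Reports pool muscles and subjects jointly by default (n = subjects × 7), as
reliability tables in this field do; per-muscle stratification and a
fat-fraction stratum (FF > 0.10, the conventional threshold for fatty
infiltration) are options. CVs are reported over subject × muscle rows;
whether published CVs pool this way or across subject means of one muscle
is ambiguous in most papers, so both are available (`cv()` is a plain
function usable either way).

# The phantom: what it emulates, and what it does not

`phantom_spec()` + `simulate_dwi()` generate a seven-compartment lower-leg
phantom: prismatic angular sectors around a central bone void, separated by
one-voxel fascia gaps, with unequal sector widths because real calf muscles
differ several-fold in volume (the soleus and gastrocnemii dominate) and
downstream between-muscle variance should reflect that. Each muscle carries
a uniform fiber field tilted from +z by its pennation angle (defaults 8–20°,
typical of the calf); the soleus and tibialis anterior are bipennate, with
the tilt sign flipping across the axial mid-plane like a central
aponeurosis.

Per-muscle diffusivities are drawn once per subject, at spec construction:
MD and FA are sampled from Gaussians centred on the cohort values implied by
the mean eigenvalues ($\lambda_1 = 1.97$, RD $= 1.39 \times 10^{-3}$ mm²/s
healthy; $1.92/1.35$ in the disease preset) with the cohort SDs of MD (0.10
/ 0.18) and FA (0.03 / 0.04), then converted to an axially symmetric
$(\lambda_1, \mathrm{RD})$ pair. Sampling MD and FA — rather than the two
eigenvalues independently — matters: group tables report the cohort spread
of MD and FA, and independent eigenvalue draws with those SDs produce FA
spreads three times wider than observed, including muscles below the FA 0.1
tracking floor. Fat is a second compartment with isotropic diffusivity
$0.2 \times 10^{-3}$ mm²/s mixed by the voxel fat fraction
($S = S_0[(1-\mathrm{FF})e^{-b g^T D g} + \mathrm{FF}\,e^{-b D_f}]$); the
healthy preset draws FF in 0.03–0.05 and the disease preset uniformly in
0.03–0.78, the range reported for neuromuscular cohorts. Noise is Rician —
two independent Gaussian channels with $\sigma = S_0/\mathrm{SNR}$, default
SNR 59 — and the sigma map records the true Gaussian σ.

Because a fat-mixed voxel is deliberately not mono-exponential, the
generator also reports the *effective* single-tensor metrics (`md_eff`,
`fa_eff`, ...) obtained by fitting the noise-free mixed signal per distinct
fiber direction and averaging with voxel counts; this — not the pure muscle
tensor — is the correct reference for parameter-recovery checks. The
distinction is visible even at FF 0.04 (about 4% in MD) and between the two
halves of a bipennate muscle (about $10^{-5}$, because the finite direction
set breaks exact rotational invariance).

`simulate_raters()` emulates two independent manual segmentations by
flipping boundary voxels: interior boundary voxels are dropped and exterior
background voxels adjacent to the label are added, each with probability
$p = 0.15 \cdot \mathrm{jitter}$, calibrated so that one voxel of jitter
leaves per-muscle Dice above 0.85 at the default geometry. Additions never
steal voxels from other muscles and are face-adjacent to the label, so no
new components appear. An optional degraded rim (`rim_voxels`,
`rim_fa = 0.07`) emulates partial-volume contamination at muscle borders:
rim voxels keep the muscle's axial diffusivity but their radial diffusivity
is raised until FA falls below the tracking floor. On such a phantom
voxel-averaged and tract-weighted means separate systematically (FA, MD and
RD shift; $\lambda_1$ barely moves, because the rim preserves it) and
method-vs-method ICC drops below rater-vs-rater ICC — the qualitative
pattern that motivates harmonising segmentation protocols.

What the phantom does **not** emulate: realistic anatomy (compartments are
idealised prisms), susceptibility and eddy artifacts, motion, fiber
curvature within a muscle, multi-peak fat spectra, or the Rician noise-floor
bias correction (at SNR 59 the bias in MD is well below the 2% recovery
tolerance, which the Monte-Carlo tests confirm). Passing the phantom checks
therefore demonstrates correctness of the estimators and the pipeline
plumbing under known ground truth — not performance on scanner data with
registration errors and anatomy-dependent partial-volume structure.

# Problem sizes and runtime choices

The default phantom grid is $64 \times 64 \times 40$ voxels at
$3 \times 3 \times 6$ mm. The acceptance experiments analyse four phantom
subjects (two raters, both strategies, all seven muscles; n = 28 pooled
pairs per rater table) and two rim-contaminated subjects at
$48 \times 48 \times 28$; unit tests use a $40 \times 40 \times 24$ fixture.
These sizes hold the full suite to a few minutes on one CPU while keeping
every muscle above 200 voxels and Monte-Carlo standard errors well below the
tested tolerances. Voxel-wise fitting and tracking run in compiled code; the
exported single-voxel R functions are the readable reference implementation,
and the test suite asserts the two paths agree to $10^{-10}$.

# Known limitations

* Deterministic Euler tracking only; no probabilistic or anatomically
  constrained variants, no tract clustering.
* Streamline I/O is TCK only (world-mm coordinates); TRK's voxel-frame
  conventions are deliberately out of scope.
* Gradient tables are FSL bval/bvec, interpreted in the image frame —
  upstream registration (with b-matrix rotation) is assumed done.
* The two-rater design is hard-wired in the reliability battery
  (k = 2 in the ANOVA decomposition and α); multi-rater designs would need
  the general mean-squares forms.
* Absolute tract-density and volume magnitudes depend on seeding density
  and phantom scale and are not comparable across tools that seed
  differently.
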