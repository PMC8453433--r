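---
title: "Methods: pre-lesion NAWM analysis on synthetic longitudinal MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-lesion NAWM analysis on synthetic longitudinal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `nawmtrack`. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

# The scientific problem

In multiple sclerosis, "normal-appearing" white matter (NAWM) — tissue
without visible lesions on conventional MRI — is diffusely abnormal, and
new T2 lesions arise preferentially in particular places, most prominently
periventricularly. Two questions drive the pipeline:

1. **Backward (pre-lesion) analysis.** In the exact tissue where a new T2
   lesion will later form, is the signal already abnormal beforehand, and
   for how long? The measures are normalized magnetization-transfer ratio
   (nMTR, myelin-sensitive), normalized T2-weighted intensity (nT2, free
   water / inflammation-sensitive) and normalized T1-weighted intensity
   (nT1).
2. **Spatial analysis.** Does the spatial distribution of NAWM
   abnormalities (patients vs healthy controls) recapitulate the spatial
   probability of lesions?

Because pre-lesion tissue is identified retrospectively (from the
*residual* part of each new lesion at end of study), and because nMTR
varies spatially but symmetrically across the midline, each pre-lesion
region is compared against two controls: the *overall NAWM* of the same
patient and the *spatially matched contralateral* mirror region. The
contralateral contrast is the spatially controlled one: any left-right
symmetric spatial structure cancels exactly.

# Normalization

* **nMTR.** For each scanner, the median MTR of grey and white matter of a
  reference healthy-control scan define an affine map sending the GM
  median to 0 and the WM median to 1; the map is then applied to every
  patient scan from that scanner. Medians commute with monotone affine
  maps, so the anchors hold exactly whatever the scanner's gain/offset;
  this is what acceptance targets t1/t2 verify. Medians with even counts
  are the mean of the central pair (R's default).
* **nT1.** Stage 1 (baseline, cross-sectional): GM median &rarr; 0, NAWM
  median &rarr; 1 (targets t5/t6). Stage 2 (longitudinal): each follow-up
  is mapped onto the baseline intensity frame by least-trimmed squares
  before the stage-1 map is applied.
* **nT2.** Stage 1: LTS onto baseline. Stage 2: z-scoring by the baseline
  NAWM mean and SD, so nT2 is in units of NAWM standard deviations
  (targets t3/t4). The SD uses the sample (n−1) convention. The statistics
  come from the *baseline* NAWM label mask and are reused at every visit;
  the anchor visit was an open choice and baseline matches the stage-1
  anchor.
* **LTS.** `moving ~ gain·reference + offset` minimizing the sum of the
  `h = ⌊fraction·n⌋` smallest squared residuals, `fraction = 0.5`.
  Optimization is the standard fast-LTS scheme: 50 elemental starts (the
  exact line through two random voxels), two concentration steps each,
  full C-step convergence for the best five candidates, deterministic
  under a fixed seed. The C-step objective is asserted non-increasing at
  every iteration, and the optimizer is tested against exhaustive-subset
  enumeration on 12-voxel instances. The fit support is whole brain
  excluding lesions at either timepoint (the support was an open choice;
  it is exposed as an argument), thinned deterministically to at most
  6000 voxels for speed — the estimator is unchanged on exact-affine
  inputs and statistically indistinguishable at this support size.

# Lesion dynamics and ROI geometry

New-lesion detection takes 26-connected components of the current T2 mask;
a component intersecting the 1-voxel dilation of the previous mask is an
*enlargement* and is excluded (the published automatic detector plus
manual review that a real study would use is out of scope; this
transparent stand-in has its two parameters — connectivity buffer and
minimum size, default 3 voxels — exposed in the configuration). Tracking
intersects the running mask with each later T2 mask; the final
intersection is the *residual*, which seeds the pre-lesion ROI.

ROI filters follow the stated criteria exactly: at least 10 voxels
(30 mm³ at 1×1×3 mm), NAWM at *all* pre-onset visits, and at least 2 mm
from any pre-existing lesion at all pre-onset visits. Numerical choices:

* Distances are exact Euclidean distances between voxel centres with
  anisotropic spacing; "at least 2 mm away" is inclusive, so a voxel at
  exactly 2.0 mm survives (acceptance target t9 pins this on a fixture
  with candidates at 1.0/1.9/2.0/3.0 mm).
* "Pre-existing" includes any lesion present at a pre-onset visit, also
  other *new* lesions that appeared before the index lesion's onset (open
  question resolved conservatively).
* The contralateral ROI is the exact mirror across the inter-columnar
  midline plane of the (even) left-right axis, so reflection is a voxel
  permutation and an involution — testable bit-exactly. Contralateral
  trimming (NAWM at all visits, ≥ 2 mm from *any* lesion at *any* visit)
  is reflected back onto the pre-lesion mask, so accepted pairs are exact
  mirrors of equal size.
* Whole-volume 2 mm exclusion zones are built by dilation with the set of
  integer offsets of physical norm < 2 mm (exactly equivalent to
  thresholding the Euclidean distance transform); per-candidate checks use
  direct distance enumeration.

# The weighted mixed-effects model

Each contrast series (lesion × pre-onset visit) is modelled as

y_ijt = x'β + b_i + b_ij + ε_ijt,  b_i ~ N(0, σ²_p),  b_ij ~ N(0, σ²_l),

with the lesion effect nested in patient, residual variance σ²/w_i with
patient weight w_i = 1/(number of accepted lesions), and AR(1) residual
correlation ρ^|t−t′| within lesion. Choices:

* **AR(1) distance** is visit *rank* by default (schedules are regular
  within a trial mode); calendar-week distance is a flag.
* **Estimation** is profiled REML: β and σ² are profiled out; the two
  variance ratios and ρ (log / atanh transformed) are optimized by
  L-BFGS-B from four spread-out starts. The blockwise restricted
  log-likelihood is tested to 1e-8 against a dense multivariate-normal
  oracle, and estimates are cross-checked against `nlme::lme` with the
  same structure.
* **LS means** per time level put continuous covariates at their weighted
  means and average categorical covariates equally over levels; tests are
  t statistics on n−p residual degrees of freedom (a pragmatic choice —
  with hundreds of observations per model the difference from
  finer-grained degree-of-freedom methods is negligible). Multiplicity
  across time levels uses Holm by default (no method was stated;
  Bonferroni and none are selectable).
* The weighting enters as relative precision, so rescaling all weights by
  a constant changes nothing (tested), and the reference level of the
  time factor is immaterial because LS means are reported per level.
* Time before onset is a categorical variable; in monthly mode the visit
  immediately before first observation (−4 weeks) is excluded from the
  analysis rows — the actual onset lies somewhere in that interval — but
  still participates in the ROI validity filters.

# The synthetic cohort: what it emulates, and what a green test means

The generator produces left-right-symmetric ellipsoidal brain phantoms
(GM shell, WM core, two mirrored periventricular CSF cavities) at
1×1×3 mm, so 10 voxels = 30 mm³. Within WM, MTR and T1w increase and T2w
decreases smoothly with distance from the ventricles; each gradient is
median-centred, so tissue medians equal the nominal tissue means exactly
(monotone maps commute with medians, and mirror duplication makes the
median an attained value). Scanner distortion is affine per channel; T1w
and T2w additionally drift affinely per visit (exactly the class of
nuisance the calibration and LTS stages remove; MTR, a ratio, drifts only
at scanner level). Noise is additive Gaussian.

Lesions are ellipsoids with semi-axes drawn from 2–6 mm, placed with
density proportional to a periventricular field `exp(−d_vent/3 mm)`,
appearing at scheduled visits (Poisson per visit). Defaults for the
injected abnormalities — a −0.1 nMTR decrement, a +0.5 SD nT2 increment,
no nT1 change, 40 % of each mirrored contralaterally, effects present
from the first simulated visit — are stated once here: the study this
emulates reports directions and significance, not magnitudes, so the
values are chosen to be physiologically plausible (a few percent of the
GM–WM MTR gap; a clearly sub-lesional T2 elevation) and are *not* tuned
against test outcomes. Patients additionally carry a diffuse NAWM nMTR
decrement of 0.12 at the periventricular peak, spatially proportional to
the same field — the abnormality that the atlas stage is designed to map.

Two injection conventions exist because two different contracts need to be
exact in the noiseless limit:

* `additive` (default): effects add to the local tissue value, so the
  pre-lesion-vs-*contralateral* contrast equals `(1−cf)·δ` exactly by
  mirror symmetry, while the vs-overall contrasts carry the genuine
  spatial offset of periventricular tissue (the very confound the
  contralateral control exists for).
* `calibrated`: the footprint injection is compensated so the
  footprint-vs-*overall-NAWM* normalized contrast equals δ exactly (a
  fixed-point iteration handles the T2 case, where injections sit inside
  the normalization statistics); used by the normalization-contract
  tests. Contralateral injections are plain additive in both modes so the
  spatial analyses see an undistorted mirror profile. A zero δ always
  means "no injection".

What the generator does **not** emulate: real MR physics (bias fields,
partial volume, motion), irregular lesion shapes, misregistration (all
phantoms share one grid — the identity-registration stand-in for the
nonlinear template registration a real study needs), tissue-segmentation
errors, and between-subject anatomical variability. A green test
therefore establishes that the *pipeline machinery* is correct and that
effects of the stated size are recovered through it — not that the
pipeline is robust to segmentation or registration failure modes.

Canonical cohort scales (fixed once): the longitudinal world uses 48
subjects at 0.5 lesions/visit (≈ 140–160 lesions, comparable to a
monthly-trial test data set); the atlas world uses 80 patients / 16
controls with many small (2–3.5 mm) lesions over one interval, because a
desk-scale empirical probability atlas needs footprints smaller than the
probability field's 3 mm e-folding length — with 2–6 mm radii the
footprint smoothing flattens the map (at study scale, n≈400+ and 1 mm
grids, this constraint disappears).

# Atlases, bins and the trend test

Mean nMTR atlases average each voxel over the subjects whose NAWM mask
covers it (coverage < 25 % of the cohort &rarr; missing, an open choice);
the abnormality atlas is HC − PwMS. The lesion-probability atlas is the
voxel-wise mask average, so `p·n` is integer-valued. Bins: the lowest bin
is anchored at `p < 0.0025`; the remaining bins are equal-width in log10 p
by default (the true edges of the reference analysis are unpublished) or
equal-count on request. The trend test aggregates to one value per
subject per bin (avoiding voxel-level pseudo-replication — the unit of
analysis was unstated), weights rows by the subject-bin voxel count, and
compares nested linear models by maximum-likelihood LRT: bin main effect
always discrete, interaction with population linear in bin index
(χ², 1 df) or discrete (n_bins − 1 df). Modelling the *main* effect as a
factor is deliberate: the spatial nMTR profile across bins is nonlinear,
and with a linear main effect its lack of fit would swamp the interaction
being tested.

# Known limitations

* The NIfTI reader/writer is minimal (single-file NIfTI-1, 3D,
  little-endian, no extensions) — sufficient for the pipeline's own
  files.
* LS-mean degrees of freedom are residual-based, not
  Satterthwaite/Kenward-Roger.
* The enlargement-vs-new classifier is a transparent geometric stand-in
  for a published detector plus manual review.
* Real-data mode would need upstream registration, midsagittal
  estimation, and tissue classification; these are declared external
  preprocessing, and the midline is assumed to be the grid mid-plane.
* With `additive` injection the vs-overall contrasts include the spatial
  offset of periventricular ROIs; simulation-based significance claims
  about those contrasts are therefore about (effect + geography), which
  matches the scientific situation, while pre-vs-contralateral isolates
  the injected effect.
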