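---
title: "Uptake-time dependence of PET radiomic features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uptake-time dependence of PET radiomic features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtpradiomics)
```

## The problem

FDG accumulates in metabolically active tissue for well over an hour after
injection, so SUV-derived quantities keep rising as the scan is delayed.
For radiomic features the consequences are subtler: some track overall
uptake, some track the evolving contrast between tumor subregions, and
some are dominated by measurement noise. A feature is only useful if one
knows (a) whether it is *repeatable* — stable between two identically
acquired scans on different days — and (b) whether its uptake-time change
is large or small *relative to* that repeatability. This package
implements the complete decision pipeline: simulate (or load) a
double-baseline dual-time-point study, delineate lesions, extract a
49-feature panel under controlled discretization, and classify every
feature into dual-time-point (DTP), cross-sectional (CS1/CS2) or
discarded use cases.

## The synthetic study model

Real double-baseline dual-time-point PET data are rare and not generally
shareable, so the package ships a generator whose statistical structure
matches what the analysis assumes, with known ground truth.

Each lesion is an ellipsoid with a flat core (60 % of the normalized
radius) and a cosine falloff to the boundary. On top of this profile sit
three controlled effects:

* **Heterogeneity.** A multiplicative log-normal texture field
  `exp(a·g − a²/2)`, where `g` is a Gaussian random field produced by
  filtering white noise with a Gaussian kernel of FWHM equal to the
  texture correlation length, standardized over the lesion patch. The
  `− a²/2` term keeps the field mean near 1 so amplitude and mean uptake
  stay separable. The field is drawn once per lesion and reused across
  all four scans — a tumor's texture does not reshuffle between days —
  while its amplitude `a` may change with uptake time
  (`heterogeneity_slope`).
* **Uptake drift.** The lesion component (not the background) is scaled
  by `1 + uptake_slope · Δt/30 min`. Scaling only the lesion mirrors the
  physiology (tumor uptake rises while background washes out slowly) and
  lets the 40 %-of-SUVmax delineation shrink slightly at the later time
  point, as a relative threshold must when lesion-to-background contrast
  grows.
* **Test–retest noise.** One multiplicative log-normal factor per
  (lesion, day, time) scan with coefficient of variation `trt_noise_cv`.
  A global factor, rather than voxel-wise noise, is what makes the
  *lesion-level* test–retest CV match the dial: independent voxel noise
  would average out as `1/sqrt(Nvox)` in every lesion summary and leave
  nothing for the repeatability analysis to measure. The suite verifies
  the calibration empirically across 300 seeds.

Finally the field is convolved with an isotropic Gaussian PSF; the FWHM
is the package's stand-in for the reconstruction: a narrow kernel (5 mm
default) emulates resolution-modelled reconstruction, a wider one a
harmonized standard reconstruction. True projection/reconstruction
physics, attenuation, scatter and motion are out of scope.

All randomness derives from the design's single seed through
per-(patient, lesion, day, time, purpose) substreams (a multiplicative
LCG fold modulo 2³¹−1), so studies are bit-reproducible and stable under
re-ordering of generation calls.

**Default conditions.** Ten patients with 1–10 lesions each (as in the
double-baseline design the generator emulates), scans on 2 days at 60 and
90 min, 4 mm isotropic voxels. Values the design leaves open were fixed
once at what a PET physicist would call a realistic NSCLC-like study:
background 1.5 g/mL; peak SUV uniform in 6–20 g/mL (relatively
high-uptake lesions); semi-axes 13–18 mm, large enough that delineated
lesions comfortably clear the 64-voxel filter; uptake slope normal with
mean 0.12 and SD 0.06 per 30 min; heterogeneity amplitude 0.3 with 12 mm
correlation; test–retest CV 0.10; PSF 5 mm. The default grid is
64×64×64 — a desk-scale stand-in chosen for test runtime; the full-size
144×144×254 grid is available through `study_design()`.

What the generator deliberately does **not** emulate: reconstruction
artifacts and spatially correlated noise, respiratory motion, lesions
abutting high-uptake organs, and patient-level correlation between
lesions. Recovery tests passing on these phantoms therefore show the
*pipeline* is correct and well-calibrated, not that any particular
clinical feature ranking will replicate.

## Delineation

Three methods, all restricted to the 26-connected component containing
the seed region's hottest voxel (so adjacent lesions never merge), all
using a closed threshold (voxel kept when SUV ≥ threshold — the
convention of the common clinical tools; the strict alternative is a
flag):

* `PCT40` — threshold at 40 % of the lesion's SUVmax, SUVmax taken
  within the seed region, not the whole body;
* `SUV4` — fixed threshold at 4.0 g/mL; lesions with SUVmax below 4
  return a degenerate, non-qualifying result rather than an error;
* `CONTRAST` — threshold at `0.5 × SUVpeak + background`. SUVpeak is the
  mean in a 1.0 mL sphere positioned (by exhaustive search over the seed
  region) to maximize that mean, sphere membership decided by voxel
  centres within the radius; at 4 mm spacing the sphere holds 19 voxel
  centres. The background is the mean SUV in a shell whose distance from
  the 70 %-of-SUVmax volume lies in [20 mm, 20 mm + one voxel pitch),
  computed with an exact Euclidean distance transform; voxels with
  SUV > 4 are excluded so neighbouring lesions cannot contaminate the
  estimate. The distance is measured from the 70 % volume's surface (the
  natural reading of "2 cm away"; measuring from the centroid would make
  the shell lesion-size-dependent).

Only lesions whose mask reaches 64 voxels qualify for feature
extraction; the filter is exact at the boundary (63 voxels → no feature
vector).

## Discretization and the 49-feature panel

Fixed bin width (FBW) assigns `level = floor((SUV − 0)/0.25) + 1` over
0–60 g/mL (240 levels, out-of-range values clamped with a warning — the
upper bound is chosen above any realistic lesion SUVmax). Fixed bin
number (FBN) rescales each lesion's own SUVmin–SUVmax range onto 64
levels, which makes every texture feature invariant to affine rescaling
of the lesion's intensities — and is exactly why FBW and FBN produce
different repeatability: FBN re-normalizes away the very drift one may
want to measure, while coupling the binning to two noisy extrema.
A degenerate lesion (SUVmax = SUVmin) maps to a single level.

The panel follows the standard LIFEx-style grouping with pinned class
sizes 6/5/6/7/11/11/3:

* conventional: SUVmin, SUVmean, SUVstd (population SD), SUVmax,
  SUVpeak, TLG = SUVmean × volume;
* shape: volume (mL and voxels), mesh surface area, sphericity
  `π^(1/3)(6V)^(2/3)/A`, compacity `A^(3/2)/V`;
* histogram: skewness, kurtosis, excess kurtosis, entropy in log10 and
  log2, energy — computed on the discretized levels, with zero-variance
  moments defined as 0;
* GLCM (7), GLRLM (11), GLZLM (11), NGLDM (3).

Texture matrices are pooled, unweighted, over all 13 unique 3-D
directions at Chebyshev distance 1 (both orientations for the GLCM,
which is therefore symmetric by construction) — one pooled matrix, not
per-direction feature averaging, matching the clinical tool the analysis
emulates. Zones are 26-connected components of equal level. The NGLDM
uses the neighbourhood gray-tone-difference formulation over the masked
26-neighbourhood; a homogeneous region has zero differences, so contrast
and busyness are 0 and coarseness is capped at 10⁶ (configurable).
Run percentage divides the pooled run count by 13 × voxels so it stays
in (0, 1]; zone percentage is zones/voxels.

Numerical corner cases are pinned by tests: GLCM correlation of a
zero-variance region is defined as 1; single-voxel regions are an error
for neighbourhood statistics; every matrix accumulator equals a naive
triple-loop enumeration oracle on 100+ random ROIs.

**Surface area.** Voxel-face counting overestimates curved surfaces by a
factor approaching 1.5 and breaks the sphericity → 1 limit, so the mask
surface is measured on a triangle mesh: the 0.5 iso-surface of the
lightly smoothed (σ = 0.75 voxel) mask indicator, triangulated by
marching tetrahedra with linear edge interpolation. The smoothing acts
as the anti-aliasing step; σ was fixed from the digitized-ball
convergence study (sphericity 0.99–1.00 for radii ≥ 8 voxels, mild
overestimation below ~5 voxels, i.e. near the qualification limit).

## Statistics and classification

For each feature (settings held fixed):

* **Uptake-time effect** — two-sided paired Wilcoxon signed-rank test on
  the day-1 values at 60 vs 90 min, exact null for ≤ 25 tie-free
  differences, normal approximation with continuity and tie correction
  otherwise, zero differences dropped (the classic rule; Pratt's variant
  was deliberately not used). Benjamini–Hochberg correction is applied
  jointly across the analyzed features, q < 0.05 significant. Lesions
  are treated as independent pairs; clustering of lesions within a
  patient is a known limitation, not modelled.
* **Repeatability** — ICC(A,1): two-way mixed-effects, absolute
  agreement, single rating, computed from closed-form ANOVA mean squares
  `(MSR − MSE)/(MSR + MSE + (2/n)(MSC − MSE))` between day 1 and day 2
  at each uptake time separately. Absolute agreement (not consistency)
  is the right form here: a systematic day effect is a repeatability
  failure. The gate is ICC > 0.9 at *both* times.
* **Effect size** — the per-lesion z score
  `((RF90 − RF60) − mean(TRT60))/sd(TRT60)` using day-1 values, with
  TRT60 the day-2 − day-1 difference at 60 min across lesions. The
  magnitude |mean z| is compared against 1: among time-affected features
  a strongly *negative* mean z is just as usable for dual-time-point
  imaging as a positive one, so susceptibility is defined on the
  magnitude.

The flowchart is a total function with four outcomes: not repeatable →
DISCARDED; repeatable and (q < 0.05 **and** |mean z| ≥ 1) → DTP;
repeatable and (q ≥ 0.05 **and** |mean z| < 1) → CS2; otherwise → CS1.
Requiring *both* criteria for DTP (and both negations for CS2) sends the
features that meet only one — statistically detectable but small, or
large but uncertain — to the "unclear" CS1 bucket; that reading
reproduces a three-way split among repeatable features and is exposed as
thresholds (`icc_gate`, `alpha`, `z_gate`) for sensitivity analyses.

## Problem sizes used by the checks

The simulation-based checks run 50 drift seeds and 50 null seeds of a
10-patient, 3-lesions-per-patient study on a 48³ grid — sizes chosen so
the whole suite stays a routine desk run while the Wilcoxon/ICC inputs
(≈ 15–25 qualifying lesions) remain comfortably above their minimums.
The drift scenario (uptake slope 0.25 ± 0.05 per 30 min, test–retest CV
0.03) and the null (slope 0, CV 0.05) are the two calibration points:
uptake-scaling features must be recovered as DTP in ≥ 80 % of seeds, and
under the null the DTP fraction must stay at or below the FDR level with
shape features never flagged. `scripts/acceptance.R` runs the
default-condition pipeline (10 patients, 1–10 lesions) end to end from a
single seed and writes the quantities it computes as JSON.

## Known limitations

* The generator's noise model is a global per-scan factor; features
  driven purely by *spatial* noise texture see less day-to-day
  variability than on real scanners.
* PSF smoothing is a surrogate for reconstruction differences; it
  reproduces resolution-driven effects (SUVmax ordering, partial-volume
  dilution) but not iteration-number or scatter-model artifacts.
* The panel's conventional/histogram membership follows the standard
  LIFEx-style list at the pinned class counts; tools differ in a few
  members (e.g. whether both kurtosis forms appear), so cross-tool
  comparisons should match features by definition, not by name.
* Voxel size is fixed per study; resampling and its interaction with
  delineation are out of scope.
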