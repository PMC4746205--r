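---
title: "Quantifying left-ventricular function from gated SPECT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying left-ventricular function from gated SPECT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvquant)
```

## The problem

ECG-gated myocardial perfusion SPECT estimates left-ventricular (LV)
end-diastolic volume (EDV), end-systolic volume (ESV) and ejection fraction
(EF = (EDV − ESV)/EDV × 100) from a 16-frame sequence of reconstructed
count images. Reconstructed SPECT resolution (≈10–15 mm FWHM) is comparable
to the cavity diameter of a small ventricle at end-systole. Counts from
opposing walls then spill into the cavity, automated edge detection places
the endocardium too far inward, ESV collapses toward zero and EF is
spuriously high. Clinically this matters because small ventricles are
common (notably in women of small body habitus), and an exaggerated EF can
mask dysfunction. `lvquant` implements a quantification pipeline with an
explicit, volume-dependent compensation for this partial-volume effect,
together with everything needed to validate it on synthetic data: a gated
phantom with analytically known volumes, contour-based reference
volumetry, 17-segment wall-motion scoring, and the method-comparison
statistics used in such validation studies.

## The estimator

`quantify_lv()` processes each gating frame independently:

1. **Mid-surface fit.** The long axis is initialised from voxels above 50%
   of the global count maximum: the centre is their count-weighted
   centroid, and the axis is the principal direction of *maximal count
   skewness*. (Plain largest-variance PCA is unreliable here: a ventricle
   is about as wide as it is long once the wall is included, whereas the
   closed apical cap skews the count distribution only along the true long
   axis. The axis is oriented base-ward by probing on-axis counts: the
   apex cap crosses the axis line, the open base does not.) Rays are cast
   on a polar grid (default 32 polar × 64 azimuthal samples, polar cap
   150°); per-ray mid-wall radii are the parabolic-refined count maxima
   along each ray, regularised by 3×3 neighbour smoothing. The centre is
   re-estimated as the axial midpoint of the fitted surface plus its mean
   lateral offset, and the fit is iterated until the centre moves less
   than half a voxel (at most 20 iterations). The axial-midpoint rule
   keeps the centre mid-cavity so that rays reach both the apex and the
   basal rim; re-centering on the mean surface point would drift
   apex-ward, because the polar grid oversamples the apex.

2. **Valve plane.** Perpendicular to the fitted axis, positioned where the
   circumferential median of counts on the mid surface falls below 50% of
   the mid-ventricular count level (the median over rings in the middle
   third of the long axis), with one-ring hysteresis and linear
   interpolation of the crossing. With symmetric blur, a half-level
   crossing is an approximately unbiased estimate of where the myocardium
   ends. Referencing the *mid-ventricular* level rather than the global
   ring maximum matters: apical rings look brighter than the free wall
   (tight curvature concentrates blurred counts), and normalising to them
   would pull the plane apex-ward, truncating the base.

3. **Edge detection.** Counts are sampled by trilinear interpolation at
   1 mm steps in a ±25 mm window around the mid surface. On each profile
   the endocardial and epicardial edges sit where the counts cross 75% of
   the profile maximum, inside and outside the maximum respectively, with
   linear interpolation between samples (`profile_edges()`). When the
   cavity counts never fall below the threshold — the small-cavity
   signature — the endocardial edge falls back to the cavity count
   minimum and the profile is flagged.

4. **Volume-dependent correction** (mode `"volume_corrected"`). Both
   surfaces are shifted outward (epicardially) along their rays by
   s(v) = 3.5·(1 − v/85)² mm, where v is the mid-ventricular volume
   measured once on the summed (non-gated) image — the volume enclosed by
   the mid-myocardial surface and the valve plane. The shift is 3.5 mm at
   v = 0, decreases to zero at 85 ml and is identically zero above 85 ml.
   Only the two anchors and the polynomial degree are established facts;
   the third condition needed to pin down a quadratic is our choice of a
   smooth junction (zero slope) at 85 ml. Any alternative is a one-line
   change in `shift_model()`.

5. **Cavity volume.** Spherical-sector summation
   V = Σ r³/3 · ΔΩ over ray cells with exact cell solid angles, each ray
   clipped at the valve plane; past the polar cap the radius field is
   padded with the last ring so the basal corner bounded by the plane is
   integrated. The quadrature is exact for constant radii with an aligned
   plane and second-order accurate otherwise (verified by refinement
   tests). EDV and ESV are the frame maximum and minimum, ties to the
   earliest frame; a heart is *small* when ESV ≤ 20 ml.

`"fixed"` mode is the identical detector with zero shift. It is **not** a
re-implementation of any commercial product; it isolates what the
volume-dependent shift changes.

## The synthetic phantom

`generate_phantom()` emulates a *reconstructed* gated study directly — no
projections, no iterative reconstruction, no attenuation or scatter
modelling (all deliberately out of scope):

* myocardium = half-ellipsoid shell, closed apex, open base truncated by a
  fixed valve plane perpendicular to the long axis; cavity long-to-short
  axis ratio 2 by default;
* the cavity volume follows a piecewise-cosine curve from EDV (frame 1)
  to ESV at the frame nearest 40% of the cycle and back, so the stated
  EDV/ESV are met exactly and the ground-truth EF is recoverable from the
  inputs;
* the wall (10 mm at end-diastole by default) thickens at end-systole so
  that myocardial volume is conserved (incompressible myocardium);
* the shell is rasterised with 2× supersampled occupancy onto a
  64×64×64 grid of 4.42 mm voxels by default (a 64-matrix camera with
  ×1.46 zoom), blurred with an isotropic Gaussian point-spread function
  (default FWHM 12 mm, typical of reconstructed perfusion SPECT), and
  optionally Poisson-sampled (noise applied after blurring — a documented
  simplification of reconstructed-image statistics);
* the frame-wise sum stands in for the non-gated acquisition.

What the phantom reproduces: the partial-volume collapse of small
end-systolic cavities, its monotone dependence on heart size, and the
fixed-vs-corrected contrast. What it does not contain: papillary and
trabecular muscles, perfusion defects, basal membranous septum, gating
jitter, attenuation artefacts, anatomical shape variability. Tests passing
on the phantom therefore demonstrate the *mechanism*, not clinical
accuracy; in patient studies the reference (cine-MR) cavity includes
papillary muscles while SPECT excludes them, which deepens the measured
underestimation at every size, ESV more than EDV.

`generate_contour_stack()` emits the exact analytic endocardial
cross-sections of the same geometry as a gapless short-axis polygon stack
(≥64 vertices per contour), standing in for manually traced cine-MR
contours; `simpsons_volume()` integrates them by disk summation
(area × thickness, the plain reading of a "modified Simpson" protocol with
gapless 10 mm slices; no basal partial-volume weighting).

## Numerical choices

* Trilinear interpolation everywhere; threshold crossings and the
  valve-level crossing by linear interpolation; per-ray count maxima with
  parabolic sub-step refinement.
* Sampling profiles are radial rays from the long-axis centre, not local
  surface normals: for quasi-ellipsoidal ventricles the difference is
  second-order, and rays make the sector volume formula exact and
  testable against closed forms.
* Degenerate inputs fail loudly: empty images, self-intersecting contours
  (with the slice index), zero-mean duplicate pairs, all-tied rank tests
  (statistic 0 with a warning), zero-variance regressors; a constant
  response in the regression is flagged rather than returned as NaN.
* Determinism: noiseless phantoms are bit-reproducible; Poisson noise is
  seeded per study (master seed + study index in sweeps and
  `run_validation()`).

### Known systematic effects

Three biases of the method itself are visible on phantoms and documented
rather than hidden:

* the count ridge of a blurred curved shell sits ≈ σ²·(curvature) inside
  the true mid-wall, so the fitted mid surface — and with it the
  mid-ventricular volume feeding the shift — runs several percent small;
  the resulting shift is slightly conservative (larger);
* the detected valve plane lands 1–2 mm apex-ward of the true basal rim,
  a volume deficit of a few percent that is larger for thin (diastolic)
  walls;
* on a *thick* end-systolic wall the symmetric 75% threshold places both
  edges slightly outside the true surfaces, so for large hearts —
  where the partial-volume mechanism is gone — the ESV error can shrink
  below the EDV error. On patient data this inversion is not observed
  because papillary-muscle exclusion (absent from the phantom) dominates
  the ESV comparison at every size.

## The validation workflow

`run_validation()` drives the full experiment from an
`experiment_config()`: phantom sweep → both quantification modes per study
(the segmentation is shared; the modes differ only in the shift) →
per-study records plus regression (`linreg_see()`), absolute and percent
Bland–Altman (`bland_altman()`, differences divided by the pairwise
average in percent mode), EF-error correlation, and small-heart counts per
mode. The acceptance tests run two sweeps at the study conditions
(64³ grid, 16 frames, FWHM 12 mm, noiseless — about two minutes of
compute): eight sizes with truth ESV 10–100 ml at fixed EF 60%, and a
six-study cohort in which size and EF anti-correlate (EDV 90→32 ml as EF
rises 45→70%), mirroring clinical populations where the small hearts are
the high-EF ones; a fixed-EF sweep cannot expose an EF-dependent error at
all. On these sweeps the fixed-mode ESV error grows monotonically in
magnitude as the heart shrinks, the correction shrinks the small-heart
ESV error and weakens the EF-dependence of the EF error, and the
small-heart count can only fall under correction.

Wall-motion agreement between two score sets uses quadratically weighted
kappa (`weighted_kappa()`, weights 1 − (i−j)²/(k−1)²), cross-checked in
the tests against the equivalent disagreement form
1 − Σo·d / Σe·d. Segmental scores come from per-segment mean endocardial
excursion with configurable cut-points (5, 2, 0.5, −0.5 mm for grades
0–4) — an invented stand-in for visual grading, clearly labelled as such.

## Limitations

Beyond the phantom simplifications above: the statistical shape prior of
commercial delineation software is replaced by the parametric mid-surface
fit; basal-plane manual correction is not modelled; the 75% threshold is
applied per sampling profile (the alternative regional-maximum reading
would change small-heart behaviour); kappa standard errors are omitted;
and the excursion cut-points for wall-motion grades have no published
counterpart, so cross-method score tables from real data should be
imported rather than regenerated.
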