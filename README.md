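# lvquant

Left-ventricular quantification from ECG-gated myocardial perfusion SPECT,
with a volume-dependent edge correction for small hearts.

## The problem

Gated SPECT estimates end-diastolic volume (EDV), end-systolic volume
(ESV) and ejection fraction (EF = (EDV − ESV)/EDV × 100) by delineating
the left ventricle on each of 16 cardiac frames. Reconstructed SPECT
resolution (FWHM ≈ 10–15 mm) is comparable to the end-systolic cavity of a
small ventricle, so counts from opposing walls merge, automated edge
detection collapses inward, ESV is underestimated and EF overestimated —
progressively more as the heart shrinks. `lvquant` is aimed at nuclear
cardiology researchers and scientific programmers who want an open,
testable implementation of a quantification pipeline with an explicit
compensation for this partial-volume effect, plus the machinery to
validate it: a synthetic gated phantom with analytically known volumes,
contour-based reference volumetry, 17-segment wall-motion scoring, and
method-comparison statistics.

## The method

Per frame: a mid-myocardial surface is fitted on a polar ray grid (count
ridge along each ray, iterative re-centering); a valve plane is placed
where mid-surface counts drop below 50% of the mid-ventricular level; the
endocardial and epicardial edges sit where each count profile crosses 75%
of its maximum, symmetrically on both sides of the wall; the cavity volume
is the spherical-sector integral of the endocardial radii bounded by the
valve plane. In `volume_corrected` mode both surfaces are first shifted
outward (epicardially) by

  s(v) = 3.5 · (1 − v/85)² mm  for v ≤ 85 ml,  s(v) = 0 above,

where v is the mid-ventricular volume (mid surface + valve plane) measured
once on the summed, non-gated image — a decreasing quadratic anchored at
3.5 mm for v = 0 and 0 mm at 85 ml. EDV/ESV are the frame extrema; a heart
is *small* when ESV ≤ 20 ml. The statistics layer provides least-squares
regression with the standard error of estimate, Bland–Altman limits of
agreement (absolute and percent-of-average), the variance-ratio F test,
quadratically weighted Cohen's kappa, and the usual rank tests
(Friedman, Kruskal–Wallis, Wilcoxon signed-rank, Dunn).

## Worked example

A small-heart phantom (truth: EDV 50 ml, ESV 20 ml, EF 60%) at typical
camera conditions — 4.42 mm voxels, 12 mm FWHM blur, noiseless:

```r
library(lvquant)
spec  <- phantom_spec(edv_true = 50, esv_true = 20, total_counts = 0)
study <- generate_phantom(spec)

quantify_lv(study, edge_params(mode = "fixed"))
#> Gated LV quantification (fixed mode)
#>   EDV 40.0 ml   ESV 14.5 ml   EF 63.7%
#>   small heart (ESV <= 20 ml): yes

quantify_lv(study, edge_params(mode = "volume_corrected"))
#> Gated LV quantification (volume_corrected mode)
#>   EDV 42.6 ml   ESV 16.0 ml   EF 62.6%
#>   small heart (ESV <= 20 ml): yes
#>   edge-correction shift 0.50 mm (mid-ventricular volume 52.8 ml)
```

The fixed detector underestimates ESV by 5.5 ml (−27%) and inflates EF by
3.7 points; the volume-dependent shift recovers part of both. The analytic
contour stack of the same phantom, integrated by disk summation, serves as
the reference method and reproduces the ground truth:

```r
ed <- generate_contour_stack(spec, phase = 1, slice_thickness = 2)
es <- generate_contour_stack(spec, phase = 7, slice_thickness = 2)
lv_function_from_stacks(ed, es)[c("edv", "esv", "ef")]
#> EDV 49.9 ml, ESV 20.0 ml, EF 60.0%
```

Agreement of ordinal wall-motion scores between two methods uses
quadratically weighted kappa; the package bundles two published 5×5
score contingency tables (748 segment observations) as examples:

```r
weighted_kappa(example_wall_motion_tables()$fixed)
#> Weighted kappa (quadratic weights): 0.713  (p_o = 0.9929, p_e = 0.9752, n = 748)
```

`run_validation(experiment_config(...))` chains phantom sweep → dual-mode
quantification → comparison report (records CSV + JSON summary), and
`inst/cli/lvquant` wraps the same functions for shell use.

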