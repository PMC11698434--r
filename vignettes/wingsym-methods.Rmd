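---
title: "Quantifying anterior-posterior wing asymmetry: methods and design"
author: "wingsym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying anterior-posterior wing asymmetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingsym)
```

## The scientific problem

The *Drosophila* wing is conspicuously asymmetric along its
anterior-posterior (AP) axis: the intervein territories between the
longitudinal veins L1-L5 and the margin M differ strongly in size, most of
all between the anterior-most (L1-L2) and posterior-most (L5-M) regions.
wingsym implements the quantitative machinery needed to measure this
asymmetry at two developmental stages — adult wings, via landmark
morphometrics, and third-instar wing discs, via the geometry of the
*vestigial* quadrant-enhancer (vgQE) expression domain — and to compare a
control cohort against a cohort in which cell recruitment (the
Vg-propagating mechanism that expands the wing pouch) has been genetically
impaired.

## Landmark shape comparison

Wings are represented as ordered, labeled 2D landmark configurations
(`landmark_config`), in image coordinates (origin top-left, x = column,
y = row increasing downward). Two landmark families are supported: margin
landmarks (ML, 10 points on the wing outline, four of them constructed by
extending the crossvein lines to the margin with
`crossvein_margin_point()`) and vein landmarks (VL, 10 points on the
venation), plus the AP-paired sets SYM10 and EXT26 used for symmetry
scoring.

`superimpose()` performs two-configuration Procrustes superimposition:
both configurations are centered on their centroids and scaled to unit
root-sum-of-squares size; the second is then rotated (improper rotations
permitted) and rescaled to minimize the sum of squared distances to the
first, computed in closed form by SVD. The minimized residual sum is the
**disparity** — dimensionless, non-negative, zero exactly for
similarity-equivalent shapes, and symmetric in its arguments because of the
standardization.

Two design points deserve explanation:

* **Reflections are allowed** in the orthogonal alignment, and
  configurations are additionally normalized to a common handedness
  (`normalize_chirality()`, which mirror-flips any configuration whose
  boundary landmark loop has negative signed area). Wings are routinely
  digitized without recording body side; without these two measures,
  left/right mixing would masquerade as shape difference.
* **Pairwise, not generalized, Procrustes.** Cohorts are compared by
  exhaustive pairwise superimposition (`pairwise_disparities()`: all
  n(n-1)/2 within-cohort pairs, or all n1 x n2 cross-cohort pairs — e.g.
  52 controls x 20 impaired wings = 1040 comparisons), not by iterative
  consensus fitting. Average aligned landmark positions are obtained by
  arithmetic averaging of the aligned matrices (`mean_aligned_shape()`),
  and `landmark_displacements()` flags landmarks displaced more than twice
  the mean inter-landmark displacement (strict inequality — the literal
  reading of "twice more than the average").

## Symmetry scoring

For the AP-paired landmark sets each anterior landmark iA has a posterior
counterpart iP (L2 paired with L5, L3 with L4 on the real wing). The **AP
axis** is the line through the midpoints of pairs 2 and 5 (`ap_axis()`).
The **anteriorized** wing replaces each iP with the mirror image of iA
across this axis (`symmetrize()`); the posteriorized wing conversely. The
axis is always computed from the original configuration, and the
symmetrized configuration keeps the original label order, so Procrustes
correspondence with the original stays label-wise. Reflection is an
isometric involution and symmetrization is idempotent per side; both are
verified to machine precision in the test suite.

A wing's symmetry scores (`symmetry_scores()`) are its disparities to its
own anteriorized and posteriorized images: (0, 0) for a perfectly
mirror-symmetric wing, growing with AP asymmetry, and invariant under
similarity transforms of the wing. `cohort_symmetry_comparison()` compares
the per-wing scores of two cohorts with the gated test described below.

## Disc-pattern geometry

The disc side works on intensity images: maximum projection of confocal
z-stacks (`project_stack()`, optionally in blocks of 5 planes), background
subtraction using the mean of a 30 px square region annotated outside the
pattern (`subtract_background()`, clamped at zero), and binarization at a
fraction — default 20% — of the maximum pixel value (`binarize_pattern()`;
the threshold is strict, making tie behavior deterministic, and relative,
making the mask invariant to intensity scaling). The maximum is taken after
background subtraction on the projected image. Cleanup
(`preprocess_mask()`) removes connected components below 64 px, optionally
keeps only the largest component (ties resolved to the first label in scan
order), and smooths edges with a 5 x 5 mean filter re-thresholded at 0.5.
The underlying study names only generic "morphology" and "blur" steps;
these concrete operators and all their parameters are deliberate, exposed
choices of this package.

Pattern roundness is measured by `pattern_eccentricity()`: convex hull of
the cleaned mask (`hull_points()`), then a direct least-squares conic fit
with the ellipse-specific constraint 4AC − B² = 1 (Fitzgibbon's method in
the numerically stable Halir-Flusser block form, on coordinates normalized
for conditioning). The fit is deterministic and non-iterative, exact for
five points in general position and zero-residual for exact on-ellipse
input; eccentricity is e = sqrt(1 − b²/a²) for semi-axes a ≥ b. The same
fit applied to manually clicked hinge-pouch fold points
(`fit_hp_ellipse()`) yields an expression-independent pouch outline.

Intervein regions are obtained by partitioning the pattern mask with
manually clicked vein polylines (`segment_mask_by_veins()`). Polylines are
extended along their terminal segments to the mask bounding box (manual
clicks rarely reach the pattern edge); each foreground pixel is assigned by
counting the veins it lies strictly posterior of, with on-vein pixels going
to the anterior side (a sub-pixel bias at worst). Pixel counting — rather
than polygon construction — makes the partition exactly conservative:
relative areas always sum to 1, and the ambiguity of where a curved pattern
edge "closes" a polygon never arises. The polygon route remains available
for adult-wing annotation outlines via `polygon_area()` (shoelace formula
with a self-intersection guard), and `ellipse_region_areas()` computes the
vein sections of a fitted pouch ellipse on a rasterization scaled to at
least 150 px minor semi-axis, relative to the exact area pi a b.

## Gated statistics and power

All two-group comparisons run through `gated_two_sample_test()`:
Shapiro-Wilk on each group at alpha = 0.05; if both pass, Levene's test
(Brown-Forsythe, median-centered) selects the equal-variance or Welch
t-test; if either fails, a two-sided Mann-Whitney U test. Every gate
outcome is recorded. Constant (zero-variance) groups make Shapiro-Wilk
undefined; such comparisons are flagged degenerate and carry no p-value.
The Mann-Whitney p-value uses exact enumeration when both groups have at
most 8 untied observations, and otherwise the normal approximation with tie
and continuity corrections; both branches are cross-checked against
`wilcox.test()` in the tests.

`mwu_power_mc()` estimates Mann-Whitney power by Monte-Carlo simulation:
samples of size n from unit-variance normals separated by the stated shift,
default 10000 repetitions, mandatory seed (bit-identical results under the
same seed). The sampling model and repetition count are this package's
choices — the simplest faithful Monte-Carlo design for a location shift —
and a bootstrap mode resampling two observed samples is available as an
alternative, not the default. `t_test_power()` gives exact noncentral-t
two-sided power, checked in the tests against an independent quadrature of
the noncentral-t tail. No multiple-testing correction is applied anywhere;
comparisons are reported per test.

## Synthetic data: what it emulates, and what it does not

No raw wing images or landmark data accompany the study this package
operationalizes, so validation rests on generators with exact ground
truth.

`template_wing()` is a fixed, exactly mirror-symmetric 10-point
configuration (span 5, half-height 1.3, AP axis = x-axis, positive loop
area). `generate_wing_cohort()` displaces its posterior landmarks outward
from the axis by `asym * w_i` of their axis distance with weights
w = (1:5)/5 — maximal at pair 5, mimicking the posterior-margin
localization of the real effect — and adds isotropic Gaussian landmark
noise. The noise default, 0.002 of centroid size, is the digitization-error
scale of wing landmark data (roughly one pixel on a high-resolution wing
image); the generator models landmark measurement error only. It does
**not** model biological shape variation, allometry, sex differences or
correlated landmark displacements, so passing recovery tests demonstrates
the correctness of the measurement chain, not robustness to every source of
real-data variance. With zero noise the anteriorized score is strictly
increasing in `asym`, and the mapping from `asym` to disparity is
documented empirically by the tests rather than claimed analytically.

`generate_disc_phantom()` renders a filled ellipse (default a = 200,
b = 120 px in a 512 x 512 image, i.e. eccentricity 0.8, pattern intensity
200 over Gaussian noise of SD 10 — intensities typical of an 8-bit confocal
projection) plus an intervein channel carrying dark vein stripes at
fractions (0.2, 0.4, 0.6, 0.8) of the major-axis extent. Ground-truth
region counts come from direct coordinate comparison inside the generator —
a code path independent of the vein-polyline partition used by the
analysis — so recovery tests are non-circular. At these noise levels the
20%-of-max threshold recovers the pattern essentially exactly; cohort
studies therefore add between-disc variability by varying the ellipse
parameters per disc, as the tests do.

## Numerical choices and degenerate inputs

* Disparities below numerical zero are clamped at 0; configurations with
  zero centroid size (all landmarks coincident) are rejected.
* A degenerate AP axis (coincident pair-2 and pair-5 midpoints) is an
  error; scheme validation reports missing labels and axis degeneracy
  without throwing.
* The ellipse fit rejects non-elliptical conics (discriminant test) and
  collinear input; orientation is reported in [0, pi) with a >= b enforced
  by eigenvalue ordering.
* Crossvein margin construction returns, among multiple margin
  intersections, the one nearest the crossvein midpoint, and is invariant
  to the margin polyline's direction of travel.
* Problem sizes used in the shipped validation: 100-replicate cohort
  simulations at n = 50 per group, 512 x 512 phantoms, 36000-angle grids
  for the Procrustes oracle, and 10000-20000 Monte-Carlo repetitions for
  power — sizes at which every quantity is stable to well within its
  stated tolerance.

## Known limitations

* Landmark identity is the user's responsibility: the anatomical
  definitions of the classical 6 margin points and the extended 26-point
  set are not encoded, and the 26-point AP pairing must be supplied
  explicitly (unpaired labels are rejected at validation rather than
  silently passed through).
* Automatic landmark or vein detection is out of scope; veins, folds and
  background regions are manual annotations (JSON).
* Fluctuating-asymmetry decomposition across left/right wings of one
  animal is not implemented; wings are treated as independent.
* The pixel partition sidesteps, but does not resolve, the biological
  ambiguity of where the vgQE pattern ends laterally; the hinge-pouch
  ellipse variant exists precisely as an expression-independent
  alternative.
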