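---
title: "Quantifying vitreous parainflammation from OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vitreous parainflammation from OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Hyalocytes — the macrophage-lineage immune cells resident in the vitreous —
appear in optical coherence tomography (OCT) as small hyperreflective
opacities floating above the retina. Their number, size, brightness and
shape track the activation state of the innate immune response, which makes
the vitreous a uniquely accessible window on neuroinflammation: unlike the
retina, it is optically homogeneous, so bright specks on the dark
background can be segmented and measured automatically. `vitreoct`
implements the full measurement chain for rodent posterior-pole scans:

1. **Layer segmentation** — find the internal limiting membrane (ILM) and
   the retinal pigment epithelium (RPE) band per column; everything above
   the ILM is vitreous.
2. **VIT/RPE relative intensity** — mean vitreous gray level divided by
   mean RPE gray level, per B-scan, averaged over the 61 B-scans of an
   eye. Using the RPE (the brightest, most stable band) as the reference
   normalizes away device gain, so the ratio is a turbidity/inflammation
   proxy.
3. **Opacity detection** — a horizontal-edge filter, Otsu binarization,
   connected components restricted to the vitreous, and an intensity
   outlier fence that separates cells from speckle.
4. **Morphometrics** — per region: area in µm², mean gray intensity,
   equivalent-ellipse eccentricity and orientation; soma-size
   classification into isolated cells (< 10 µm²), non-activated cells
   (10–50 µm²), activated cells (50–250 µm²) and cell complexes
   (> 250 µm²).
5. **Cohort statistics** — per-eye summaries across groups
   (two ocular-hypertension glaucoma models, MEPI and Ms, against healthy
   controls) and weeks (0–24), with KS normality screening, one-way ANOVA,
   Tukey HSD, Pearson correlations between timepoints and Bonferroni
   control.

Because the in-vivo scans behind the original study are not publicly
deposited, the package ships a synthetic B-scan generator with exact
planted ground truth; every accuracy claim the package makes is computed
against that ground truth by the test suite and `scripts/acceptance.R`.

## Calibration

The posterior-pole protocol acquires 61 B-scans of 1536 × 496 pixels
covering 3 mm laterally and 0.969 mm axially. Two per-pixel-area
conventions are possible: squaring the lateral pitch,
(3000/1536)² = 3.815 µm², or multiplying lateral by axial pitch,
1.953 × 1.954 = 3.816 µm². The instrument-reported figure of 3.815 µm² is
reproduced only by the square-pixel convention, so that is the default
(`default_calibration()`); `square_pixel = FALSE` selects the rectangular
alternative. The total image area follows as
1536 · 496 · 3.815 µm² = 2.906 mm². Note the nominal "3 µm per pixel"
device resolution is not consistent with either pitch; the calibration
follows the internally consistent 3.815 µm² figure.

## Segmentation

The boundary finder is deliberately simple and column-wise:

* **ILM** — the vitreous background level is estimated robustly (median
  plus 3 MAD-based SDs) from the top 10% of rows; robust statistics
  matter because planted or real cells can cross the estimation window.
  Scanning down each column, the retina begins at the first position
  where the 5-px axially smoothed intensity stays above threshold for at
  least 20 consecutive samples. The long run requirement (rather than the
  2–3 samples one might first try) is what prevents a bright vitreous
  cell — up to ~10 px tall — from capturing the boundary and masking
  itself out of the vitreous. The run start is then refined to the first
  raw above-threshold pixel, so on a noise-free scene the recovered ILM
  equals the planted row exactly.
* **RPE band** — below the ILM plus a 20-px guard offset, the band peak is
  the brightest smoothed position; its inner/outer limits are where the
  smoothed profile falls below half the peak's elevation over the sub-ILM
  median. A column fails if the peak rises less than 40 gray levels above
  that median (no bright band present).
* Both curves are median-filtered over 15 columns and failed columns are
  linearly interpolated, so every B-scan yields full-width masks. The
  vitreous mask is strictly above the ILM; the RPE mask is the inclusive
  band; they are disjoint by construction.

All window widths, the threshold multiplier, the run length, the guard
offset and the contrast floor are exposed in `segmentation_params()`.

## Detection and the two noise regimes

Detection per B-scan (`detect_opacities()`) follows the chain *edge
emphasis → Otsu → label → fence → measure*:

* the 3 × 3 kernel `[[1,2,1],[0,0,0],[-1,-2,-1]]` approximates a vertical
  gradient and so emphasizes horizontal edges; the signed response is
  rectified (absolute value) so bright-over-dark and dark-over-bright
  transitions both contribute;
* Otsu's threshold is computed over a 256-bin histogram (integer gray
  levels when the image is integral) by maximizing between-class
  variance; inside an empty histogram gap every split is equivalent, and
  the mid-gap mean is returned. Foreground is *strictly above* the
  threshold, so a constant image has empty foreground;
* components are 8-connected (switchable to 4) and restricted to the
  vitreous mask shrunk by 2 rows above the ILM — the edge kernel responds
  to the vitreoretinal step itself one row into the vitreous, which would
  otherwise contribute a spurious full-width band;
* the speckle fence keeps a region only if its mean gray intensity
  strictly exceeds the Tukey upper fence (Q3 + 1.5·IQR, type-7 quantiles)
  over all candidate regions of that B-scan; fewer than four candidates
  give a fence of +∞ (nothing passes — a handful of regions cannot define
  a noise population);
* surviving regions are measured from the grayscale image under the
  binary mask.

The fence deserves its own paragraph, because its statistical premise
decides how the pipeline should be configured. Q3 + 1.5·IQR marks *upper
outliers of the candidate population*. On raw in-vivo scans that
population is hundreds-to-thousands of speckle-induced regions per B-scan
with a few tens of genuine cells — the cells are true outliers and the
fence isolates them (the test suite reproduces this regime with
single-frame-strength speckle, gamma shape 3). But when candidate regions
are *mostly cells* — high planted counts under light noise, or any
noise-free image — the quartiles land inside the cell-intensity
distribution and the fence removes essentially everything, including all
cells when their intensities are similar. This is not a bug; it is what
the rule means. Consequently:

* `detection_params()` (fence on, no hole filling) is the profile for
  noise-dominated, in-vivo-like data;
* `synthetic_detection_params()` (fence off, closing + hole filling on)
  is the profile for the light-speckle synthetic scenes used in
  validation, where false candidates are rare and the planted truth is a
  *filled* ellipse rather than an edge outline.

The hole-filling step exists because an edge filter produces contours:
the filled contour carries a one-pixel response shell outside the true
boundary, which is peeled off before measurement. With speckle the shell
surrounds the region (noise activates the kernel in every direction) and
a full one-pixel erosion is used; in a noise-free image the
vertical-gradient kernel leaves no lateral shell and a vertical-only peel
is correct (`peel = "vertical"`, selected by
`synthetic_detection_params(noiseless = TRUE)`). Regions thin enough to
vanish under the peel keep their full extent. A genuine blind spot
remains in noise-free images: a near-vertical elongated cell presents
almost no horizontal edge, so its contour cannot close and it fragments.
With speckle present the interior lights up and the blind spot
disappears; this is documented rather than patched because it is a
property of the published filter choice.

## Morphometrics

Region shape is summarized by the equivalent ellipse of the second
central moments, with the 1/12 pixel-extent correction added to both axis
variances so a single pixel is a well-defined circle (eccentricity 0).
Eccentricity is √(1 − λ₂/λ₁) — 0 for a disc, approaching 1 for a
zero-width segment. Orientation is the half-angle of the principal
eigenvector, degrees in (−90, 90], measured from the image x-axis with
counterclockwise positive (row index increases downward); a region with
equal eigenvalues reports 0° by convention. Area is the pixel count times
the calibrated pixel area — a one-pixel opacity measures 3.815 µm², which
is why the isolated-cell class (< 10 µm²) is 1–2 pixels at this pitch.

Per-eye summaries (`summarize_eye()`) pool the opacities of all B-scans:
mean count per B-scan, total area, and per class the count, percentage,
and mean area/intensity/eccentricity/orientation. Orientation is averaged
as *signed degrees* by default, so opposed orientations cancel and a mean
returning to zero indicates loss of a common heading; the circular
(axial) mean is available via `circular_orientation = TRUE`.

## The synthetic generator

`render_bscan()` builds a layered scene — dark vitreous (gray 25), mid
retina (110), bright 8-px RPE band (230), flat ILM at 40% height by
default, all configurable per column — stamps non-overlapping elliptical
opacities, records the ground-truth label masks *before* noise, then
applies multiplicative gamma speckle and quantizes to 8-bit. A pixel
belongs to a planted ellipse iff its center satisfies the ellipse
inequality (boundary included); a sub-pixel ellipse falling between
pixel centers plants its nearest pixel.

The speckle model is multiplicative gamma with mean 1 and variance
1/shape. The default shape of 25 (20% intensity SD) represents the
residual speckle of frame-averaged acquisition with active eye tracking —
the regime of the posterior-pole follow-up protocol; shape 2–4 emulates
raw single-frame speckle and is used in the tests that exercise the
fence. What the generator does *not* emulate: motion and blink artifacts,
vascular shadowing, depth-dependent signal roll-off, the optic-nerve-head
region, and real hyalocyte morphology (planted cells are ellipses).
Passing the synthetic benchmarks therefore demonstrates correctness of
the measurement chain under the stated image model, not clinical
performance on in-vivo scans.

Opacity populations are described by `opacity_model()`: a per-B-scan
count distribution, a soma-size class mix (areas uniform within each
class interval), truncated-normal intensities, uniform eccentricities
(0.80–0.97, matching the reported 0.85–1 range) and uniform orientations.
The two stock models encode the study's reported regimes:
`control_opacity_model()` plants 10–20 opacities per B-scan with the
non-activated class dominant, and `glaucoma_opacity_model()` plants
Poisson(70) opacities with ≈45% activated. Placement is
rejection-sampled with a clearance margin (5 px) and a 4-px gap above the
ILM. `cohort_design()`/`generate_cohort()` assemble eyes × groups ×
weeks (controls only at weeks 0/12/24) with a documented counter-derived
seed chain — master seed → per-eye → per-B-scan — so any single image is
regenerable in isolation and identical master seeds reproduce every
image and CSV byte-for-byte.

`reduced_cohort_design()` is the fast benchmarking profile: 384 × 124 px
(4× downscale, rescaled calibration) with pixel-scale size intervals
(scaled by 0.25) because the micron-scale classes are sub-pixel at that
pitch, and a 3-px clearance. At this density the non-overlap constraint
caps achieved glaucoma counts somewhat below the Poisson target
(typically ≈60–65 planted per B-scan against a nominal 70); ground truth
always records what was actually planted.

## Statistics

The statistical stage is intentionally thin wrappers with explicit
contracts: `ks_normality()` is a Monte-Carlo Lilliefors test (the KS
statistic against a normal with *estimated* mean/SD needs a simulated
null; the classical KS table would be anticonservative), `anova_oneway()`
is the classical equal-variance F test, `tukey_hsd()` the
studentized-range post-hoc, `pearson_corr()` the product-moment
correlation with t-based p, and `bonferroni_adjust()` α/m.
`cohort_stats()` applies them across metrics × weeks and correlates
metrics between weeks within groups, pooled and per sex. A dedicated
calibration test checks the ANOVA's empirical type-I error over 10,000
null simulations stays at 5% ± 1.5 points.

## Validation sizes and reproduction

The test suite and `scripts/acceptance.R` compute everything at sizes
chosen to run comfortably on one CPU: oracle equivalence uses 100 random
images (Otsu), 1,000 random masks (labeling) and 200 random regions
(moments); the detection benchmark uses 6 full-resolution B-scans of the
glaucoma model (~285 planted cells) at default speckle, plus a dedicated
3-B-scan series of large cells (both semi-axes can exceed 5 px) for the
eccentricity-accuracy clause, which is conditioned on that size range; class-mix
recovery uses 20 noise-free B-scans (400 cells, orientations within
±60°, see the blind-spot note above); group separation uses 10 cohorts
(10 eyes per group, 6 reduced-resolution B-scans each); the null
calibration uses 10,000 simulated datasets. With these sizes the whole
acceptance script completes in a few minutes and reports, among others,
detection recall/precision ≈ 0.99, mean area error ≈ 10%, eccentricity
error ≈ 0.01, class-mix error < 1 point and a 10/10 group-separation
rejection rate.

## Known limitations

* The detector inherits the published filter's blind spot for
  near-vertical elongated objects in noise-free images.
* The fence is only meaningful on noise-dominated candidate populations;
  profile selection is the user's responsibility (see above).
* No volumetric merging across adjacent B-scans and no tracking across
  timepoints: a cell intersected by several B-scans is counted in each.
* The optic-nerve-head region is not excluded from the vitreous; whether
  the original analysis excluded it is unknown.
* AVI support covers uncompressed 8-/24-bit DIB streams (lossless);
  codec-compressed videos must be exported to image stacks first.
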