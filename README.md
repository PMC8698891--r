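# vitreoct

Quantification of vitreous parainflammation from OCT B-scans.

In rodent glaucoma models (and increasingly in patients), the innate
immune response shows up in optical coherence tomography as small
hyperreflective opacities — hyalocyte/microglia-lineage cells — floating
in the vitreous above the retina. `vitreoct` measures them. Given a
per-eye series of cross-sectional B-scans (61 scans of 1536 × 496 px
covering 3 mm × 0.969 mm in the reference protocol), the package:

* segments the **internal limiting membrane (ILM)** and the **retinal
  pigment epithelium (RPE)** band per image column, yielding vitreous and
  RPE masks;
* computes the **VIT/RPE relative intensity** — mean vitreous gray level
  over mean RPE gray level, per B-scan, averaged over the series — a
  turbidity/inflammation proxy;
* detects **hyperreflective opacities** in the vitreous: horizontal-edge
  emphasis with the kernel `[[1,2,1],[0,0,0],[-1,-2,-1]]`, Otsu
  binarization (within-class variance minimization over 256 bins),
  8-connected components restricted to the vitreous, and a speckle
  denoiser that keeps only regions whose mean intensity strictly exceeds
  the Tukey upper fence Q3 + 1.5·IQR of the candidate population;
* measures each opacity from its equivalent ellipse (second central
  moments with the 1/12 pixel-extent correction): area in µm²
  (3.815 µm²/px at the default calibration), mean intensity,
  eccentricity √(1 − λ₂/λ₁) and orientation in (−90°, 90°], and assigns
  the soma-size activation class — isolated (< 10 µm²), non-activated
  (10–50 µm²), activated (50–250 µm²), complex (> 250 µm²);
* summarizes eyes over time and runs the cohort statistics (KS/Lilliefors
  normality, one-way ANOVA, Tukey HSD, Pearson correlations between
  weeks, Bonferroni correction).

Because the underlying in-vivo scans are not publicly deposited, the
package also contains a first-class **synthetic B-scan generator** with
exact planted ground truth (layered anatomy, multiplicative gamma
speckle, elliptical cells with configurable count/size/intensity/
eccentricity/orientation distributions, longitudinal multi-group cohort
designs). All accuracy claims are validated against that ground truth.

## Worked example

Generate one synthetic glaucoma-model eye (≈70 planted cells per B-scan)
and analyse it end-to-end:

```r
library(vitreoct)

gen <- generate_series(scene_spec(), glaucoma_opacity_model(),
                       n_bscans = 6, seed = 42,
                       animal_id = "MEPI-01", group = "MEPI", week = 4)
res <- analyze_eye(gen$series,
                   pipeline_config(detection = synthetic_detection_params()),
                   keep_series = FALSE)
print(res)
#> Eye analysis: animal MEPI-01 RE (MEPI, female), week 4
#>   VIT/RPE relative intensity: 0.1173
#>   opacities: 430 total, 71.67 per b-scan, 42438.5 um^2 total area
#>   size classes (%): isolated 9.8, non_activated 39.5, activated 45.1, complex 5.6
```

The eye carries 71.7 opacities per B-scan (the glaucomatous regime; a
healthy control eye runs at 10–20), a VIT/RPE ratio of 0.117, and ~45% of
cells in the activated 50–250 µm² class. Comparing the detections with
the planted truth by intersection-over-union matching:

```r
print(run_benchmark(gen))
#> Synthetic detection benchmark
#>   planted: 430 (295 large), detected: 430, matched: 424
#>   recall 0.986 (large-only 0.993), precision 0.986
#>   area rel. error: median 0.056, mean 0.098
#>   eccentricity error (mean abs): 0.0722
#>   class-mix error: 1.86 percentage points
```

`analyze_cohort()` stacks per-eye summaries over a whole design and
`cohort_stats()` runs the ANOVA/Tukey/Pearson stage on them. A thin CLI
(`inst/scripts/vitreoct-cli.R`) exposes `analyze`, `simulate`,
`benchmark` and `stats` subcommands over the same functions.

The methods vignette
(`vignettes/vitreous-opacity-analysis.Rmd`) documents the segmentation
and detection algorithms, the two detection profiles (the upper-fence
denoiser needs a noise-dominated candidate population; the synthetic
profile replaces it with closing + hole filling), the speckle model, and
all numerical conventions.

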