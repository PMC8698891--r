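Package: vitreoct
Title: Vitreous OCT Hyperreflective Opacity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies vitreous parainflammation from optical coherence
    tomography (OCT) B-scans. Segments the internal limiting membrane and
    the retinal pigment epithelium band, computes the VIT/RPE relative
    intensity, detects hyperreflective vitreous opacities (horizontal-edge
    filtering, Otsu binarization, vitreous-restricted connected components,
    Tukey upper-fence speckle denoising), measures equivalent-ellipse
    morphometrics (area, intensity, eccentricity, orientation), classifies
    opacities into soma-size activation classes, and summarizes longitudinal
    cohorts with ANOVA/Tukey/Pearson statistics. Includes a synthetic B-scan
    and cohort generator with exact planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, nortest, optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
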