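Package: ftirfp
Title: ATR-FTIR Metabolic Fingerprinting of Cell Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for attenuated total reflectance Fourier-transform
    infrared (ATR-FTIR) metabolic fingerprinting of cultured cells. Reads
    two-column, wide-CSV and minimal JCAMP-DX spectral exports; preprocesses
    spectra (rubberband or linear baseline correction, total-area
    normalization, Savitzky-Golay second derivatives); performs
    region-restricted principal component analysis with side/quadrant group
    discrimination readouts and loading-peak band assignment; computes lipid
    intensity ratios (CH2/CH3, carbonyl/total lipid, unsaturated/saturated)
    from second-derivative peak intensities; and runs a nonparametric test
    battery (Kruskal-Wallis, Dunn-type many-to-one post hoc, Mann-Whitney U,
    Welch's t, D'Agostino K-squared normality screen). A synthetic cohort
    generator with Gaussian band profiles, baseline drift and noise provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
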