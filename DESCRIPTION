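Package: leakfit
Title: Curve-Fit Quantification of Dye-Penetration Microleakage in Crown Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures dye-penetration microleakage and cement-layer thickness on
    RGB cross-section images of cemented crown specimens. Penetrated dye is
    segmented by per-channel RGB thresholds, traced with single-pixel markers
    along the die-cement interface, and summarised by the arc length of a
    fitted fourth-order polynomial, converted to millimetres by a microscope
    calibration factor with a complete-penetration cap. Includes a synthetic
    cross-section generator with analytic ground truth, the accompanying
    statistical workflow (a-priori sample size via the noncentral F
    distribution, Shapiro-Wilk normality gate, Kruskal-Wallis omnibus test and
    Bonferroni-adjusted Dunn pairwise comparisons), and a command-line
    interface for study-level batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
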