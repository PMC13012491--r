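Package: cdresp
Title: Cadmium-Responsive Soil Bacteria from Calorimetry and Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for identifying cadmium-responsive soil
    bacteria. Combines Gompertz-based kinetic analysis of paired
    control/Cd-spiked isothermal-microcalorimetry thermograms (cumulative
    heat integration, nonlinear least-squares fitting of Q_max, mu_max and
    lag, peak detection, paired spiked-vs-control deltas), bias-corrected
    compositional differential abundance across soil-Cd categories and
    experiment timepoints (structural-zero screening, sampling-fraction
    offsets, per-taxon log-linear contrasts with Benjamini-Hochberg
    correction), community diversity and ordination statistics (Chao1,
    Shannon, Kruskal-Wallis with Dunn letters, Bray-Curtis, PERMANOVA,
    constrained principal-coordinates ordination), and the set-logic
    classification of Cd-responsive taxa. Ships a synthetic-data generator
    emulating the field design so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
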