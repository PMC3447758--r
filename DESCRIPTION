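Package: pwnimpact
Title: Economic Impact Assessment of Pine Wood Nematode Invasion in
    European Forests
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Bioeconomic assessment of an uncontrolled pine wood nematode
    (Bursaphelenchus xylophilus) invasion of European conifer forests.
    Couples a stochastic presence/absence range-expansion simulator with
    climate (mean summer temperature) and host standing-stock layers,
    integrates the layers at coarse (region) and fine (1 km2 cell)
    resolution, computes cumulative and marginal direct losses by partial
    budgeting over six host vulnerability classes, and propagates the
    accumulated stock loss through a calibrated constant-elasticity
    partial-equilibrium model of the EU industrial round-wood market to
    obtain consumer, producer and total welfare changes. Includes the
    single-parameter, worst/best-case and data-layer-removal uncertainty
    analyses, a synthetic world generator for fully reproducible runs,
    and Esri ASCII grid / CSV input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
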