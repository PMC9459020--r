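Package: ommatid
Title: Agent-Based Simulation of Arthropod Eye Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Off-lattice agent-based simulator of arthropod eye development.
    A virtual morphogenetic furrow sweeps a two-dimensional epithelium of
    circular precursor cells from right to left; distance-gated events behind
    the furrow specify evenly spaced R8-like founder photoreceptors, recruit
    three successive photoreceptor waves and layers of border (pigment/support)
    cells around each eye unit, and prune remaining undifferentiated cells by
    apoptosis. Seven parameter presets reproduce qualitatively distinct eye
    layouts (fly-like compound eye, spaced stemmata, ocelli, and single-chamber
    eyes arising by expansion or fusion). Includes lattice metrics (founder
    spacing, unit censuses, radial wave profiles, label autocorrelation),
    deterministic save/reload of epithelia, event logging, and SVG/PNG
    snapshot rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
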