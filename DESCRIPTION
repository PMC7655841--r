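Package: calcmech
Title: Micromechanics of Biogenic and Geological Calcite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative micromechanics of calcite single crystals, built
    around uniaxial micro-pillar compression. Converts raw force-displacement
    records to normalized engineering stress and strain with a Sneddon-type
    substrate-compliance correction for slightly tapered pillars, and extracts
    Young's modulus, yield strength, maximum strength, elastic limit, failure
    strain, strain bursts, and plastic-flow plateaus. Fits two-parameter
    Weibull strength distributions by rank regression or maximum likelihood
    with bootstrap uncertainties. Enumerates the twin and slip systems of
    calcite (e, r, f) in Miller-Bravais indices and computes Schmid factors
    for arbitrary uniaxial loading of the hexagonal structural cell.
    Implements a wing-crack micromechanical model relating the spacing and
    inclination of nanoscopic intracrystalline defects to compressive
    strength, an Inglis-type stress-concentration anisotropy for elliptical
    defects, and precipitation-strengthening estimates from hardness
    contrast. Quantifies defect populations from digitized contours by
    direct least-squares ellipse fitting, nearest-neighbour spacing, and
    orientation-versus-boundary-distance profiles. Seeded generators
    produce synthetic compression curves, strength samples, and spatial
    defect fields for end-to-end testing of the analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
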