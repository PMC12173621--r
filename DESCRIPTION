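Package: delimech
Title: Biaxial Mechanics and Sensory Texture Analysis of Thin Meat Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of planar biaxial extension tests of thin food sheets
    such as deli meat slices. Converts raw biaxial force-displacement
    recordings to Piola stress-stretch curves, fits incompressible isotropic
    hyperelastic models (neo-Hookean and Mooney-Rivlin) by linear least
    squares, and discovers sparse two-term strain-energy models from an
    eight-term invariant library by L1-regularized gradient descent.
    Companion sensory-texture statistics score validated food questionnaires,
    summarize Likert texture panels, run per-feature one-way ANOVA, and
    correlate physical stiffness with sensory features by Spearman rank
    correlation with exact permutation p-values at small sample sizes. A
    seeded synthetic-data generator emulates biaxial recordings (five loading
    modes, loading/unloading hysteresis, multiplicative noise) and survey
    panels with known ground truth. Ships a packaged dataset of mean
    stress-stretch measurements for eight commercial deli products.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
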