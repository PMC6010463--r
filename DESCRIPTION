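Package: microtumor
Title: Compartmental Modelling and Image Quantification of Enzyme
    Gradients in 3D Microtumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and simulates a four-compartment reaction model of a
    tumor spheroid in which a clamped extracellular nutrient diffuses
    through concentric shells and is consumed by expression of a
    proliferation factor ('Ki67'), the serine-synthesis enzyme PHGDH, and
    (in the M2 variant) a core-derived inhibitor of PHGDH expression.
    Mass-action ordinary differential equations are derived from a
    serializable rule inventory, integrated to steady state, and
    summarised as outer-layer-normalized compartment profiles. Companion
    modules generate ground-truthed synthetic fluorescence images of
    microtumor cross-sections and cell monolayers, and quantify them by
    radial linescans, compartment means, and per-cell intensities, so the
    emergent nutrient and inhibitor gradient predictions can be checked
    against image-derived profiles without experimental data.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
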