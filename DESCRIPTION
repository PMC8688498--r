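Package: gelgraft
Title: Quantification Pipelines for Hydrogel-Mediated Retinal Cell Transplantation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipelines for characterising enzymatically crosslinked
    gelatin/hyaluronic-acid interpenetrating-network (IPN) hydrogels used as
    vehicles for retinal ganglion cell transplantation, together with
    synthetic-data generators carrying known ground truth. Includes passive
    microrheology (mean square displacement, generalized Stokes-Einstein
    moduli, gel-point detection), selective enzymatic degradation fitting and
    IPN composition inference, live/dead viability segmentation with watershed
    splitting and shape-factor morphometry, dual-threshold engraftment
    segmentation with retinal-layer assignment and orientation analysis,
    Pearson/Manders co-localization statistics, and gel-retina interface
    attachment and OCT gel-mass quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    stats,
    utils,
    tiff,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
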