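Package: scalefilm
Title: Thin-Film Optics and Thickness Metrology for Butterfly Scale Laminae
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse thin-film interference modelling of the lower
    lamina of butterfly wing scales. Provides a Fresnel reflectance model of a
    single chitin film averaged over a microscope objective's illumination
    cone, a Gaussian surface-roughness variant, pigment filtering, inverse
    estimation of lamina thickness from adwing reflectance spectra,
    microspectrophotometry spectral processing, helium-ion-microscopy
    working-distance and tilt corrections, hierarchical group comparison with
    permutation inference, natural-breaks color grouping, colorimetric
    rendering of model spectra, and a synthetic-data generator emulating
    nested thickness datasets and noisy reflectance spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
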