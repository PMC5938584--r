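Package: heliris
Title: Structural Colour and Visual Modelling of Heliconius Wing Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking butterfly wing-scale nanostructure to
    perceived iridescent colour. Provides processing and summary of
    angle-resolved reflectance spectra (smoothing, negative clamping,
    min-zero normalisation, peak and bandwidth extraction), a transfer-matrix
    multilayer reflectance model of the ridge lamellae with the first-order
    constructive-interference prediction, ridge-spacing estimation from
    small-angle X-ray scattering images (radial integration, background
    subtraction, peak refinement) and from AFM height maps (windowed 2-D
    Fourier power spectra), receptor-noise-limited colour discriminability
    for avian and Heliconius visual systems (von Kries quantum catches,
    tetrahedral colour space, chromatic and achromatic just-noticeable
    differences), per-taxon summary tables and the ridge-spacing versus
    brightness correlation, and seeded synthetic-data generators emulating
    the spectrometer, SAXS detector and AFM instruments so that every stage
    is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
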