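Package: skinoptics
Title: Multispectral Skin Chromophore Mapping with a Two-Layer
    Kubelka-Munk Model and Genetic-Algorithm Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstruction of skin reflectance cubes from multispectral
    camera images and retrieval of five physiological skin parameter maps
    (melanosome volume fraction, epidermis thickness, haemoglobin volume
    fraction, oxygenated haemoglobin fraction, dermis thickness).
    Provides offset/flat-field calibration of raw monoband images, a
    linear heteroassociative-memory spectral reconstruction trained on a
    24-patch chart, wavelength-dependent chromophore absorption models,
    a two-layer (epidermis over dermis) Kubelka-Munk forward model of
    diffuse skin reflectance, and a bounded real-coded genetic algorithm
    that inverts measured spectra into skin parameters.  A synthetic
    acquisition chain (illuminant, interference filter bank, optics,
    sensor) and skin phantom generator make the whole pipeline testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
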