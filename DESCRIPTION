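Package: fcbtrace
Title: Hyperspectral 3DCOS-ResNet Traceability and Multielement Quality
    Analysis of Fritillariae Cirrhosae Bulbus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multidimensional quality evaluation and geographic traceability
    analysis for Fritillariae Cirrhosae Bulbus (FCB), the dried bulbs of
    Fritillaria cirrhosa. Converts visible/near-infrared hyperspectral
    reflectance spectra (400-1000 nm, 300 channels) into generalized
    synchronous three-dimensional correlation spectroscopy (3DCOS) images and
    classifies them with a 12-layer residual convolutional network, alongside
    a NIPALS PLS-DA baseline with VIP scores. Also provides radiometric
    calibration against a 20%-reflectance panel, ROI mean-spectrum
    extraction, calibration-curve alkaloid quantification, blank-corrected
    mineral-element content computation from microwave-digestion records, and
    element-alkaloid correlation analysis. A synthetic-data generator
    emulates the five-source study design (5 classes x 18 bulbs, absorption
    bands at 750/800/840/970 nm) so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
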