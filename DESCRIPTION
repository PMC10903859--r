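Package: alveoquant
Title: Quantification of Pulmonary Fibrosis and Alveolar Airspace in
    Stained Whole Lung Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Headless, scriptable quantification of fibrosis extent and
    alveolar airspace availability in whole lung-slice RGB micrographs
    stained with Sirius Red or Masson's trichrome. Provides calibrated
    raster and ROI containers, dual-threshold segmentation with
    particle analysis (area, perimeter, circularity), distance-based
    pleura and air-duct wall definition, parenchyma extraction, color
    deconvolution of Masson's trichrome, negative-space alveolar
    morphometry, overlay visualization, a seeded synthetic lung-slice
    generator with pixel-exact ground truth, and an end-to-end batch
    pipeline in which every stage records its settings in a
    reproducibility ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    tiff,
    png,
    jpeg,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
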