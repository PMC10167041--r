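Package: valve3d
Title: Ex Vivo MicroCT Morphometry of Calcified Aortic Valve Cusps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative 3D image analysis of ex vivo microfocus computed
    tomography (microCT) scans of calcified aortic valve cusps. Provides slice
    stack input/output with gray-value normalization against reference
    materials, cusp and calcification segmentation, multilevel Otsu threshold
    selection, a partial-volume-effect correction protocol that decomposes
    calcifications into low/moderate/high density classes, 3D connected
    particle morphometry with a micro/meso/macro size classification, local
    thickness mapping (largest inscribed sphere), synthetic cusp phantom
    generation with ground truth for validation, and group comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
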