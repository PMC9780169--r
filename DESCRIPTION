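Package: woundpatch
Title: Patient-Specific Wound-Filling Scaffold Design and Print Validation from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Digital workflow for turning a volumetric CT image of an open
    soft-tissue wound into a patient-specific, uniform-thickness hydrogel
    patch design with printable toolpaths, and for validating printed or
    implanted scaffolds quantitatively. Provides synthetic CT phantom
    generation with analytic ground truth, threshold/connected-component
    wound segmentation, distance-transform shell construction, median
    smoothing, marching-tetrahedra surface extraction, a minimal planar
    slicer with perimeters and regional rectilinear infill emitting
    volumetric G-code, trimmed-ICP rigid registration with cloud-to-cloud
    deviation gauging, interface void detection with void-volume statistics,
    contact-area conformality analysis, and a contralateral mirror-and-
    subtract workflow for designing scaffolds from the uninjured limb.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
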