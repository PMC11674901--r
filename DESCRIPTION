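Package: fpdgen
Title: Parametric Support Generation for Fixed Partial Dentures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated, parametric generation of tooth-type and implant-type
    supports for a 4-unit fixed partial denture (FPD) as solver-ready triangle
    meshes. Provides a self-contained mesh kernel (multi-solid STL I/O,
    boundary-loop extraction, oriented bounding boxes, plane sectioning,
    normal offsets, lofting, Boolean operations), FPD alignment, support-type
    detection via a cross-section circularity index, Bezier-profile root and
    periodontal-ligament construction, helical-thread implant modelling,
    insertion into a layered mandibular bone segment with saucer-shaped
    crestal defect carving, and the associated bone and periodontal-ligament
    material models (Misch D1-D4 qualities, graded transition zone,
    first-order Ogden hyperelasticity). Deterministic synthetic fixtures
    stand in for scanned geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
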