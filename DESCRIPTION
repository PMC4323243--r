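Package: cephaloplane
Title: Landmark-Oriented Reference Planes for 3D Cephalometric Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and comparison of landmark-oriented horizontal
    reference planes (four Frankfort horizontal plane variants and the
    lateral semicircular canal plane) and derived midsagittal planes from
    named 3D cephalometric landmarks, as used in cone-beam CT analysis of
    orthognathic surgery patients. Provides bilateral dental
    distance-asymmetry metrics, signed midline symmetry offsets, observer
    reliability statistics (mean absolute coordinate differences and
    Pearson correlation), Friedman cross-plane comparison, rigid
    cranial-base superimposition, plane-bounded region clipping of closed
    triangle meshes, voxel-based volume differencing, and the
    soft-to-hard tissue average-movement ratio. Includes a synthetic skull
    landmark and mesh phantom generator with closed-form ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
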