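Package: histovol
Title: Serial-Section Histology to 3D Voxel Volume Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a registered, classified 3D voxel volume from a
    stack of serial 2D fluorescence histology sections. Provides contrast
    normalization, red-channel positive-staining marking, Gaussian
    smoothing and down-sampling, landmark-based rigid (rotation plus
    translation) registration, three-class intensity segmentation
    (positive / negative / non-tissue background), nearest-neighbour
    repair of damaged slices, seeded 3D region growing to remove
    extra-organ noise, majority-label volume down-sampling, and output as
    legacy ASCII VTK structured-points files. Includes a synthetic
    serial-section generator with full ground truth (applied per-slice
    transforms, voxel labels, landmark sets) so that every stage of the
    pipeline can be validated without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
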