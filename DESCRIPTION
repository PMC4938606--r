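Package: lungkin
Title: Diaphragm and Chest-Wall Mechanics from Dynamic 3D Lung Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies respiratory muscle mechanics from time-resolved 3D
    lung segmentations. Extracts watertight lung surface meshes from binary
    masks, partitions them into costal, medial and diaphragmatic regions
    with a curvature watershed and an anatomically seeded random walker,
    tracks the surface through a breathing maneuver via a supplied
    deformation field, and computes geometry and motion features (lung
    volumes, cranio-caudal and antero-posterior size ratios, region-wise
    swept volumes, diaphragm excursion and dome orientation) together with
    unfolded 2D excursion maps. Includes a synthetic dynamic lung phantom
    with analytic ground truth, mask preprocessing utilities (Otsu
    thresholding, iterative bias-correction masking, physical-space
    morphology, Dice overlap) and measurement-agreement and group-comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
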