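Package: mtlatlas
Title: Probabilistic Atlas Construction and Sulcal Conformation Statistics
    for the Medial Temporal Lobe
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds voxelwise probabilistic maps (occurrence maps) of medial
    temporal lobe structures from cohorts of co-registered binary masks, and
    implements the statistical machinery used to compare sulcal morphological
    conformations of the rhinal and collateral sulci: Gaussian smoothing and
    fraction thresholding of occurrence maps, bounding-box extrema and
    centroid permutation tests between conformation types, orthogonal
    distance regression line fits to centroid clouds with direction
    comparison, and cohort-level proportion, t-test and phi-coefficient
    statistics with false discovery rate control. Includes a synthetic
    cohort generator that rasterizes tubular sulcal imprints with the two
    conformation types (connected versus separated rhinal and collateral
    sulci), so the full pipeline is testable without access to MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
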