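Package: spindlekit
Title: AP-MS Interactome Hit Calling and 3D Mitotic Spindle Geometry
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two complementary analyses of centrosome biology.
    First, a deterministic filtering cascade for tandem-affinity-purification
    mass spectrometry (AP-MS) pulldowns: per-replicate unique-peptide evidence
    is collapsed to a non-redundant protein list, contaminants observed in
    untagged or other-bait control pulldowns are excluded, proteins are tiered
    by replicate-presence and unique-peptide thresholds, and the resulting
    interactor list is assembled into a bait-centric weighted network with
    GraphML export. Second, 3D quantification of centrosome-spindle pole
    geometry in multichannel fluorescence stacks with anisotropic voxels:
    intensity-threshold segmentation, spindle-axis fitting with a z-separation
    selection rule, centrosome-to-pole angles and back-edge distances,
    centrosomal marker intensity, and per-cell phenotype classification.
    Exact Fisher and Wilcoxon rank-sum tests for the resulting small-sample
    group comparisons, and synthetic-data generators (peptide evidence sets
    and voxelized mitotic cells with known ground truth) for validation, are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tools,
    utils,
    tiff,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
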