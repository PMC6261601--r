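Package: lptcmorph
Title: Morphometry of Lobula Plate Tangential Cells from EM Skeleton Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the morphometric analysis of neuron skeleton
    reconstructions from serial block-face electron microscopy volumes,
    centred on the tangential cells of the fly lobula plate. Reads and
    writes KNOSSOS/webKnossos NML, SWC and hoc skeleton formats; resamples
    skeletons to a uniform internode spacing; estimates neurite volume
    from per-node diameter annotations with a frustum model; builds a
    two-surface model of the lobula plate from an expert outline and
    assigns every skeleton node a normalized anteroposterior depth and a
    layer (1-4); measures pairwise axon-axon contact areas in the medial
    tract by constrained morphological dilation of a voxelized
    representation; and solves global tile montage positions for the
    underlying image grid from pairwise cross-correlation shifts by
    weighted least squares. A synthetic-data module generates
    radius-annotated skeletons spanning a curved plate, intertwined axon
    bundles and noisy overlapping tile grids with known ground truth, so
    every stage of the pipeline can be validated without the original EM
    volume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    interp,
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
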