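Package: cowlabel
Title: Anatomical Labeling of the Circle of Willis in Cerebrovascular
    Centerline Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies the six major bifurcations and fourteen arteries of
    the Circle of Willis in vessel centerline graphs derived from CTA
    segmentations.  Candidate vessel segments are selected by a landmark
    distance score after rigid iterative-closest-point alignment of a
    per-artery landmark atlas; each bifurcation is then matched by
    recursively maximizing a path score over all edge-simple vessel paths
    leaving a candidate node, and the six bifurcation sub-graphs are fused
    into one consistent labeling.  Includes a distance-driven baseline
    labeler, a synthetic cerebrovascular phantom generator with stroke
    occlusions, anatomical variants and segmentation artifacts, and an
    automatic evaluation of labelings against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
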