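Package: clusteridif
Title: Supervised-Clustering Image-Derived Input Functions for Dynamic Brain PET
Version: 0.1.0
Authors@R:
    person("Imaging", "Methods Lab", email = "idif@example.org", role = c("aut", "cre"))
Description: Fully automated extraction of an arterial input function from
    dynamic brain PET images. Voxel time-activity curves are classified by
    supervised clustering (non-negative least squares against gray-matter,
    white-matter and blood template curves), carotid and surrounding-tissue
    masks are built from averaged blood-weight images, the carotid curve is
    corrected for partial-volume loss and tissue spill-in with a small number
    of arterial blood samples, and radiometabolites are removed with a
    monoexponential parent-fraction model. The corrected plasma input feeds
    Logan graphical analysis of the total distribution volume. A synthetic
    dynamic-PET phantom generator with full ground truth (whole-blood curve,
    two-tissue-compartment kinetics, carotid geometry, point-spread blur,
    reconstruction-like noise) makes every stage testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
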