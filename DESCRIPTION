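Package: derivHiC
Title: Derivative-Chromosome Reconstruction and Simulation of Cancer Hi-C
    Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs and simulates cancer Hi-C contact maps under
    structural variations. Builds derivative chromosomes from breakend
    records (DEL/DUP/INV/TRA with 3to5/5to3/3to3/5to5 orientations) or from
    user-specified fragment-order text, remaps binned contact matrices onto
    the rearranged coordinates, applies sequential interactive-style edits
    (delete, invert, duplicate, join) with undo, normalizes contacts by
    coverage and by distance-expected background (observed/expected
    fold change), scores cross-junction contact continuity, and generates
    synthetic Hi-C matrices with known ground-truth rearrangements for
    validation. Includes publication-style heatmap rendering and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
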