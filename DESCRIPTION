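Package: atlaskit
Title: Construction and Use of Integrated Single-Cell Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and using large integrated single-cell
    transcriptomic atlases: preprocessing filters and gene/label
    harmonization across datasets, a one-dimensional common coordinate
    framework for airway anatomy, entropy-based cluster quality control,
    k-nearest-neighbour label transfer with calibrated uncertainty,
    hierarchical pseudo-bulk marker gene selection, principal-component
    regression for covariate variance attribution, and uncertainty-driven
    discovery of disease-associated cell states. Includes a synthetic
    multi-dataset atlas generator with planted ground truth for validating
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
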