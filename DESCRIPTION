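Package: phatr
Title: Automatic Phylogenetic Reference Trees and Multilevel Placement Utilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building phylogenetic reference trees from
    taxonomically annotated sequence databases and for working with
    phylogenetic placement data. Implements entropy-guided taxonomy
    expansion to select clades, per-clade consensus sequence
    construction, taxonomic constraint trees, multilevel ("backbone plus
    clade tree") placement routing with monophyly checks and an analytic
    cost model, cross-sample read deduplication with chunking and
    abundance-aware resolution of placement results, and placement
    accuracy metrics (weighted topological and branch-length distances
    to expected edges, EDPL, clade identification accuracy, taxonomic
    assignment). Reads and writes aligned FASTA, semicolon-delimited
    taxonomy tables, edge-numbered newick and jplace (v3) JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Biostrings,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
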