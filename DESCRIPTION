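Package: ppiAlign
Title: Multiple Local Alignment of Protein-Protein Interaction Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@ppialign.org",
           role = c("aut", "cre"))
Description: Detects conserved protein complexes across two or more
    protein-protein interaction networks by stochastic multiple local
    network alignment.  Seed rows of mutually similar proteins (BLAST bit
    scores or shared orthology-group membership) are located by Gibbs
    sampling, extended greedily while the aligned subgraphs grow denser,
    and refined by iterative node swaps.  Includes an index of structural
    conservation (ISC), overlap-based deduplication of alignments, text
    and GraphML exporters for alignment graphs, a synthetic benchmark
    generator with planted conserved complexes, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'ppiAlign-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'accessors.R'
    'io-network.R'
    'io-similarity.R'
    'io-annotations.R'
    'align-engine.R'
    'align-phases.R'
    'scoring.R'
    'io-alignment.R'
    'synthetic.R'
    'cli.R'
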