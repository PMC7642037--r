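Package: coexfun
Title: Gene Co-Expression Networks, Functional Modules, and Promoter
    Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Species-agnostic toolkit for gene-function analysis from an
    expression compendium: signed co-expression network construction with
    scale-free-topology cutoff selection, weighted (WGCNA-style) functional
    module detection via topological overlap and eigengene merging,
    over-representation gene-set enrichment with hypergeometric, Fisher and
    chi-squared tests and six multiple-testing corrections, empirical
    promoter cis-element enrichment against a random-gene-list null, and
    ortholog-based (interolog) projection of protein-protein interaction
    networks. Includes a synthetic-data generator with known ground truth
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
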