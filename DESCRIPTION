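Package: phyloscape
Title: Scalable Phylogenetic Tree Layouts Linked to Community Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Draws large phylogenies alongside community (sample-by-feature)
    data. Trees are stored as succinct balanced-parentheses bit vectors with
    constant-time navigation, sheared to the features of a table, laid out
    with rectangular, circular, or unrooted equal-angle algorithms, and
    annotated with tip-level metadata barplots, uniform-clade collapsing,
    and bidirectional sample-to-node selections against an ordination.
    Includes a sliding-window builder that turns dated, located records
    into community samples for longitudinal analysis, deterministic fixture
    generators, and static SVG export with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    grDevices,
    withr
LinkingTo: Rcpp
Suggests:
    ape,
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
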