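Package: pktopo
Title: Topological Classification and Enumeration of RNA Pseudoknots
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the topological analysis of pseudoknotted RNA
    secondary structures. Structures read from extended dot-bracket, CT or
    BPSEQ files are decomposed into irreducible and then primitive
    (irreducible and non-nested) components; each component's genus is
    computed by counting the closed loops of its chord diagram, and its
    stem-collapsed shadow is named by a canonical pseudoknot pattern token
    (ABAB, ABACBC, ...). A depth-first tree-building algorithm enumerates
    all distinct primitive pseudoknot shadows with a given number of arcs,
    binned by genus, with an exhaustive perfect-matching oracle for
    validation. A classification pipeline tabulates pseudoknot subclasses
    and total-genus histograms over structure datasets, and a seeded
    generator plants known motifs in synthetic structures for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
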