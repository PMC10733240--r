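Package: orchardgen
Title: Injective Generation, Counting and Canonical Encoding of Orchard and
    Tree-Child Phylogenetic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rooted binary phylogenetic networks that can be reduced
    to a single leaf by iterated cherry and reticulated-cherry reductions
    (orchard networks), and for the tree-child and stack-free subclasses.
    Networks are encoded injectively by their minimum complete reducible-pairs
    sequence, a canonical cherry-picking sequence, and the package generates,
    counts and randomly samples all orchard, tree-child or stack-free networks
    with a prescribed number of leaves and reticulations by a depth-first
    search over such sequences that never materializes the networks
    themselves. Also included: sequence/network conversion in both directions,
    recognition and canonicalization of input networks, isomorphism testing,
    extended Newick import/export, an independent brute-force cross-check, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
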