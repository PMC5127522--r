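Package: dcite
Title: Cladistic Information Content of Alignments and Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the cladistic information in multiple sequence
    alignments before tree building. Implements the dCITE score (deflated
    Cladistic Information based on Total Entropy): per-site Shannon
    entropies summed over an alignment, deflated by removing duplicate
    sequences and sites whose split pattern recapitulates an earlier
    site's. Also provides the companion alignment metrics Delta_min, Total
    CIC / I(chi) and character diversity, tree-side diagnostics
    (degeneracy, tree CIC, minimum clade support) on Newick trees, a
    taxon-addition saturation analysis with plateau detection, a synthetic
    fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
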