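Package: fvseof
Title: Flux Variability Scanning Based on Enforced Objective Flux with
    Grouping Reaction Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene amplification targets for metabolite
    overproduction in genome-scale metabolic models. Implements flux
    variability scanning based on enforced objective flux (FVSEOF) under
    grouping reaction (GR) constraints: functionally coupled reactions,
    supplied as a genomic-context group file, are tied by simultaneous
    on/off binaries and by flux-scale couplings gated on equality of
    flux-converging pattern (CxJy) indices. Reactions whose flux bias
    rises as the product flux is stepped from its minimum to its
    theoretical maximum are classified, partitioned into strong and weak
    candidates, and ranked by flux capacity. Includes an SBML reader and
    writer, a stoichiometric LP/MILP layer, toy-network generators with a
    brute-force oracle, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    igraph,
    Matrix,
    pracma,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
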