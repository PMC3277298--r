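Package: caenophylo
Title: Phylogeny, Character Mapping and ITS2 Barcoding for Caenorhabditis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discrete-character parsimony mapping (Fitch, Sankoff,
    ACCTRAN, constrained single-origin counting) on the 26-species
    Caenorhabditis phylogeny, ITS2 barcode-gap analysis with explicit indel
    handling (one change per gap), parsimony branch lengths on
    species-constrained strain trees, and GTR+Gamma+I divergence estimation
    by pruning likelihood with branch-length optimization on a fixed
    topology. Ships the Caenorhabditis fixture topology and phenotypic
    character matrix, plus seeded simulators of character, sequence and
    multi-strain barcode data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
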