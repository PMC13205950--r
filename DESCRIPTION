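Package: mitocub
Title: Codon Usage Bias Analysis for Mitochondrial Protein-Coding Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage bias in mitochondrial
    protein-coding genes. Loads coding sequences from FASTA or GenBank flat
    files, applies CDS quality filters, and computes per-gene usage indices
    (positional GC content, synonymous third-position composition, RSCU,
    Wright's effective number of codons, CAI, CBI, Fop, GRAVY, aromaticity).
    Implements the standard mutation-versus-selection diagnostics (neutrality
    plot regression, ENC plot with expected curve and ENC-ratio binning, PR2
    parity plot), correspondence analysis of gene-by-codon RSCU matrices,
    optimal-codon identification from ENC-stratified expression groups via
    delta-RSCU, and multi-species RSCU hierarchical clustering with Newick
    export. Includes a seeded synthetic coding-sequence generator with
    controllable per-family codon frequencies so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
Suggests:
    ape,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
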