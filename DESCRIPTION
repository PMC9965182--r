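Package: strainprimer
Title: Strain-Specific PCR Primer Design and Attachment qPCR Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing bacterial strain-specific PCR and qPCR
    primers from genome comparisons. Finds reference-genome regions absent
    from a panel of near-neighbor query genomes (k-mer seeded, ungapped
    extension), enumerates and ranks primer pairs under configurable design
    constraints with nearest-neighbor melting temperatures, screens
    candidate pairs by in silico PCR with a 3'-end mismatch specificity
    rule, and predicts ribosomal intergenic spacer (RISA) fingerprints.
    Also implements absolute quantification for attachment qPCR assays:
    DNA copy number from mass and genome size, standard-curve fitting with
    amplification efficiency, Ct-cutoff calling, bacteria-to-plant
    normalization, and nonparametric group comparison with compact letter
    displays. Includes seeded synthetic-data generators so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
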