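Package: coidiag
Title: COI Barcode Diagnostics for Species Identification and Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and auditing a mitochondrial COI DNA-barcode
    reference library and for diagnosing unknown specimens against it.
    Implements Kimura 2-parameter distances with pairwise deletion,
    barcode-gap and divergence-overlap analysis, neighbour-joining trees with
    nonparametric bootstrap supports and a monophyly-based species
    differentiation tally, a Bayesian species/subspecies assignment test based
    on the coalescent distribution of segregating sites, and in-silico
    restriction typing of COI amplicons with NlaIII and BamHI (the two-enzyme
    'NB' haplotyping system used in gypsy moth surveillance). A seeded
    simulator generates multi-species barcode libraries with known truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
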