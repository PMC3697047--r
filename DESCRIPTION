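Package: tetractivity
Title: Weighted Degenerate-Tetranucleotide Sequence-Activity Models for Mature miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative sequence-activity relationship (QSAR) toolkit for
    mature microRNA sequences. Computes position-weighted abundances of
    degenerate (IUPAC) tetranucleotides, screens the full space of weighted
    tetranucleotide features for robust correlation with a measured activity
    using a 77-test utility score over seven bootstrap-style data subsets,
    verifies candidate features by a permutation test, and applies published
    linear models linking tetranucleotide features to miRNA abundance and
    Argonaute (Ago2/Ago3) loading affinity, including an ill-posed
    inverse-problem range calibration, a limiting-stage abundance estimator,
    and a two-cluster single-linkage control analysis. Ships the two training
    tables (17 Arabidopsis 20-nt fragments; 12 human 22-nt fragments) as
    plain-text fixtures and a seeded synthetic-data generator with planted
    tetranucleotide signals for engine validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
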