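Package: retrocomp
Title: Base Composition, Codon Usage and Mutation Spectra of
    Non-LTR Retrotransposon Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sequence-composition and codon-usage statistics for coding
    sequences of transposable-element consensus families and their host
    genes: mono- and dinucleotide composition with observed/expected
    dinucleotide ratios, codon-position GC content, polyadenylation-signal
    scanning, RSCU, Wright's effective number of codons (Nc), the Codon
    Adaptation Index with its randomization-based expectation (CAI/eCAI),
    and the Relative Codon Deoptimization Index with its expectation
    (RCDI/eRCDI).  Also implements a singleton-based de novo mutation
    spectrum for families of genomic copies aligned to their consensus,
    with CpG-context classification and opportunity normalization, and a
    synthetic-data generator (host CDS sets, element consensus sequences,
    diverged copy families under a substitution model with CpG
    hypermutability) so every stage can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
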