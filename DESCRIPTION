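Package: neuropep
Title: Neuropeptide Prohormone Processing, Spectrum Matching, and Motif
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico arm of invertebrate neuropeptide
    discovery: prediction of mature peptides from prohormone precursors via
    signal-peptide and mono/di/tribasic cleavage-site models with C-terminal
    amidation and N-terminal pyroglutamate rules; monoisotopic and average
    peptide masses, modification deltas, and theoretical a/b/y fragment-ion
    series; matching of theoretical peptides against centroided MALDI peak
    lists (MGF or plain text) with ppm precursor and Da fragment tolerances
    and a binomial-tail match score; degenerate sequence-motif scanning,
    consensus-pattern construction, and orcokinin-family classification;
    tissue FPKM expression profiling with reference-gene normalization; and
    a seeded synthetic-data generator producing ground-truthed precursors,
    spectra, and expression tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
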