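Package: tfbsturnover
Title: Binding-Site Turnover, Polarized McDonald-Kreitman Tests, and
    Ascertainment-Aware Site Frequency Spectra for Drosophila CRMs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the evolutionary gain, loss, and maintenance
    of transcription factor binding sites (TFBS) between Drosophila
    melanogaster and D. simulans.  Scores footprint sequences with position
    weight matrices, classifies single-nucleotide mutations by their predicted
    effect on binding affinity, polarizes fixed and segregating changes onto
    species lineages with outgroup parsimony, calls lineage-specific binding
    site gains and losses, runs generalized McDonald-Kreitman tests against a
    synonymous no-change reference, models the ascertainment bias induced by
    reference-genome footprint discovery, and builds coverage-aware site
    frequency spectra.  A synthetic-data generator emulates the structure of
    population-genomic CRM alignments with known truth so every stage of the
    pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
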