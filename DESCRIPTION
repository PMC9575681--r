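Package: markovfill
Title: Markov-Chain Gap Filling for Draft Genome Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closes N-gaps in draft genome scaffolds using long reads.
    Gaps and their flanking sequences are detected in the scaffold, long
    reads are aligned to each gap region with a seed-and-extend local
    aligner (or imported from BLAST-style tabular output), surviving
    flank alignments are extended across the gap on the read with
    strand-aware coordinate arithmetic, and the resulting candidate
    sequences train a first-order nucleotide transition table from which
    anchored Markov-chain samples are generated, scored by average
    transition probability, and spliced back into the scaffold. Includes
    a seeded synthetic-data generator (reference genome with planted
    repeats, gapped scaffold, error-containing long reads) and truth-based
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
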