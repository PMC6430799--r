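Package: chiralseq
Title: Chiral Spike-In Controls for DNA Sequencing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis of chiral (mirror-orientation) synthetic DNA
    spike-in controls ("sequins") for DNA sequencing assays. A chiral control
    is a copy of a genomic region arranged in reverse nucleotide order (no
    complementation), so it shares composition, repeat structure and entropy
    with its template while remaining alignable only to a mirrored reference.
    The package builds mirrored reference genomes, constructs sequin molecules
    and mixtures (genotype panels, variant-allele-frequency dilution ladders
    and microsatellite-instability controls), partitions and transforms
    alignments between mirrored coordinate systems, profiles per-base coverage
    and sequencing errors to measure commutability, labels variant calls
    against the known mixture truth, optimizes somatic filter thresholds to
    exclude all sequin false positives, and calls microsatellite instability
    from spanning reads with an internal resolution check. A seeded read
    simulator with context-dependent error models provides reproducible test
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
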