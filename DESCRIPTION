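Package: phageTermini
Title: Phage Genome Termini Detection and Packaging Mechanism
    Classification from Virome Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the physical ends (termini) of phage genomes from
    shotgun virome sequencing data and classifies the DNA-packaging
    mechanism of each assembled contig. Reads are mapped onto contigs by
    exact seed matching of their first bases; positions where the
    starting-position coverage (SPC) is enriched relative to a
    coverage-conditioned binomial null are called as candidate termini
    with Benjamini-Hochberg control, and the geometry of the per-strand
    peaks together with local coverage elevation discriminates 5' and 3'
    cohesive (cos) ends, direct terminal repeats (DTR) and headful (pac)
    packaging. Includes a virion read simulator that generates
    mechanism-specific genomes, sheared paired-end reads and ground
    truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    parallel,
    data.table,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
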