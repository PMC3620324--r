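Package: preyblock
Title: Design of Predator DNA Removal Strategies for Diet Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for designing predator DNA removal strategies in PCR-based
    diet analysis of generalist predators. Screens commercially available
    restriction enzymes against grouped COI barcode libraries by mapping
    degenerate recognition sites and ranking enzymes that cut the predator
    while sparing prey; profiles per-column nucleotide frequencies and Shannon
    entropy across alignments to locate variable 3' anchor sites; designs and
    validates predator-specific annealing blocking primers with per-prey-group
    mismatch probabilities; delineates prey OTUs from clone libraries by
    uncorrected p-distances and furthest-neighbor (complete linkage)
    clustering across a dissimilarity-threshold scan with plateau detection;
    and filters pseudogenes and assigns identities for clone-library QC.
    Seeded synthetic generators provide every input class for testing without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
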