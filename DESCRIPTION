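Package: gapweaver
Title: Gap Closing, Validation and Repeat Discovery for Draft Genome Assemblies
Version: 0.9.0
Authors@R:
    person("Genome", "Toolsmith", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for improving draft reference assemblies with long-read
    donor contigs. Detects N-run gaps in chromosome scaffolds, closes or
    partially closes them with anchored donor-contig sequence under a
    configurable length-deviation tolerance and a mis-ligation (shrinkage)
    guard, and records every edit in a patch ledger that supports coordinate
    liftover between assembly versions. Closed gaps are validated by
    collinearity against an independent assembly and by barcoded linked-read
    molecule coverage; scaffolded contigs are screened against optical-map
    alignments. Also discovers telomere motif arrays in raw long reads (with
    end extension of chromosomes), detects centromeric satellite monomer
    arrays and their higher-order repeat periodicity, places previously
    unplaced contigs, and tests repeat/gene enrichment of newly added
    sequence by permutation. Ships a truth-known synthetic-data generator for
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
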