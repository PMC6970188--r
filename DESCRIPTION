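Package: meiochip
Title: Simulation and Interval Statistics for Meiotic DSB Hotspot ChIP Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing binned ChIP signal over meiotic double-strand
    break (DSB) hotspots in a yeast-like genome: a seeded synthetic-data
    generator that plants hotspots, resection-flank RPA signal, gene-body
    H3K56ac enrichment and a mutant RPA map with suppressed and boosted
    hotspots; track normalization (log2 ratios against input and H3
    occupancy); threshold peak calling; relative-distance colocalization
    statistics with interval-shuffling nulls; metagene and anchor-point
    profiles; locus-level fold-change quantification; and differential
    classification of control versus mutant peak sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
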