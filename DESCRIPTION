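Package: splicescope
Title: Splice-Junction Filtering, Alternative-Splicing Event Classification
    and Differential Splicing Under Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A junction-centric pipeline for genome-wide alternative-splicing
    analysis from spliced short-read alignments. Extracts exon-exon junctions
    from CIGAR N gaps, calibrates a false-positive filter against decoy
    junctions built by splicing exons from different chromosomes, classifies
    alternative-splicing events (cassette exons, alternative 5'/3' splice
    sites, mutually exclusive and coordinate cassette exons, alternative
    first/last exons) from confident junctions, calls intron retention from
    intronic read coverage, tests differential splicing between conditions
    with Fisher's exact test on junction versus exon read counts, and
    characterises splice sites (GT/AG dinucleotides, alternative-site offsets,
    position frequency matrices). Ships a synthetic-data generator that plants
    events of every class, with known inclusion shifts, for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    Rsamtools,
    optparse
Config/testthat/edition: 3
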