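Package: ancestryPaint
Title: Subgenome Ancestry Painting and Chimeric Contig Detection for
    Hybrid Polyploid Assemblies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing chimeric assemblies of hybrid polyploid
    genomes such as commercial sugarcane. Contig alignments against two
    progenitor references (MUMmer show-coords, PAF or SAM) are reduced to
    merged ranges, each contig is assigned a subgenome ancestry, contigs
    whose segments derive from different progenitors are flagged as
    recombinant with estimated breakpoints, and genome-wide statistics
    (coverage of one genome by another, length-weighted nucleotide
    identity, read-depth copy-number partition, unplaced-contig
    concordance, repeat-class summaries) are computed. Chromosome-scale
    ancestry paintings can be exported as BED9 tracks. A seeded synthetic
    hybrid-genome generator plants known ancestry segments, breakpoints
    and collapsed repeats so the whole pipeline is testable without
    external data, and a minimal consensus-correction model quantifies
    how short-read correction of noisy long reads can chimerise
    subgenomes whose divergence is below the read error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
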