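Package: finishr
Title: Reference- and Optical-Map-Guided Finishing of Bacterial Draft Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finishing bacterial draft genome assemblies: ordering and
    orienting contigs along a reference genome or a whole-genome (optical)
    restriction-map placement report, correcting the replication start of
    circular genomes, merging neighbouring contigs that share dovetail
    overlaps, and closing inter-contig gaps by anchoring 3 kb contig flanks on
    a reference, mapping raw reads into the anchored window, and extracting
    the pileup consensus between the flank anchors. Includes a self-contained
    seed-and-extend local aligner, in-silico restriction digestion with
    map-concordance scoring, assembly metrics (N50, unknown-nucleotide
    reports), assembly-to-assembly syntenic comparison, seeded synthetic-data
    generators for desk-scale testing, and a command-line pipeline. Scaffolds
    are exported as FASTA and AGP v2.1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
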