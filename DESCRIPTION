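Package: mitosplice
Title: Splice-Site Usage and Mitochondrial Transcriptome Statistics for
    Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes gene-normalized splice-site usage (GNSSR) from
    exon-exon junction reads, partitions aligned reads between the
    nuclear and mitochondrial genomes, estimates the relative abundance
    of unprocessed polycistronic mitochondrial precursor RNA from reads
    spanning the borders of neighboring mitochondrial transcripts, and
    quantifies qPCR measurements on the 2^-dCt scale.  Includes a
    deterministic simulator that generates toy two-compartment genomes
    and aligned single-end reads with known isoform mixtures,
    mitochondrial read fractions and precursor fractions, so that every
    statistic can be validated against a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
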