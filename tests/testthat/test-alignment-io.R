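write_test_sam <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              "@SQ\tSN:chr1\tLN:5000")
  writeLines(c(header, lines), path)
  path
}

test_that("GTF coordinates convert to 0-based half-open and exons are sorted", {
  dir <- withr::local_tempdir()
  gtf <- file.path(dir, "anno.gtf")
  writeLines(c(
    paste("chr1", "test", "exon", "301", "400", ".", "+", ".",
          'gene_id "G1"; transcript_id "T1"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("chr1", "test", "exon", "101", "200", ".", "+", ".",
          'gene_id "G1"; transcript_id "T1"; gene_biotype "protein_coding";',
          sep = "\t"),
    paste("MT", "test", "exon", "1", "900", ".", "+", ".",
          'gene_id "MTG"; transcript_id "MTT"; gene_biotype "Mt_rRNA";',
          sep = "\t")
  ), gtf)
  genome <- read_annotation(gtf)
  t1 <- genome$exons[genome$exons$transcript_id == "T1", ]
  expect_equal(t1$start, c(100, 300))
  expect_equal(t1$end, c(200, 400))
  expect_equal(t1$exon_rank, c(1L, 2L))
  expect_equal(
    genome$chromosomes$compartment[genome$chromosomes$name == "MT"], "mito")
  expect_equal(
    genome$chromosomes$compartment[genome$chromosomes$name == "chr1"],
    "nuclear")
})

test_that("CIGAR walk produces the documented blocks", {
  sam <- write_test_sam(c(
    "r1\t0\tchr1\t11\t255\t100M\t*\t0\t0\t*\t*",
    "r2\t0\tchr1\t1\t255\t50M200N50M\t*\t0\t0\t*\t*",
    "r3\t0\tchr1\t1\t255\t30M5D70M\t*\t0\t0\t*\t*",
    "r4\t0\tchr1\t1\t255\t10M10N10M20N10M\t*\t0\t0\t*\t*",
    "r5\t4\tchr1\t0\t0\t*\t*\t0\t0\t*\t*",     # unmapped: skipped
    "r6\t256\tchr1\t1\t255\t100M\t*\t0\t0\t*\t*" # secondary: skipped
  ))
  al <- read_alignments(sam)
  expect_setequal(unique(al$read_id), c("r1", "r2", "r3", "r4"))
  r1 <- al[al$read_id == "r1", ]
  expect_equal(list(r1$start, r1$end), list(10, 110))
  r2 <- al[al$read_id == "r2", ]
  expect_equal(r2$start, c(0, 250))
  expect_equal(r2$end, c(50, 300))
  r3 <- al[al$read_id == "r3", ]   # deletion does not split the block
  expect_equal(list(r3$start, r3$end), list(0, 105))
  r4 <- al[al$read_id == "r4", ]
  expect_equal(nrow(r4), 3)
})

test_that("classification and junction extraction follow the block count", {
  al <- tibble::tribble(
    ~read_id, ~chrom, ~start, ~end,
    "u1", "chr1", 0, 100,
    "g1", "chr1", 0, 50,
    "g1", "chr1", 250, 300,
    "g2", "chr1", 0, 10,
    "g2", "chr1", 20, 30,
    "g2", "chr1", 40, 50
  )
  cls <- classify_reads(al)
  expect_equal(cls$gapped[match(c("u1", "g1", "g2"), cls$read_id)],
               c(FALSE, TRUE, TRUE))

  jx <- extract_junctions(al)
  expect_equal(nrow(jx), 3)  # block count - 1 per read
  expect_equal(jx$donor_end[jx$read_id == "g1"], 50)
  expect_equal(jx$acceptor_start[jx$read_id == "g1"], 250)
  g2 <- jx[jx$read_id == "g2", ]
  expect_equal(g2$donor_end, c(10, 30))
  expect_equal(g2$acceptor_start, c(20, 40))
  expect_equal(nrow(extract_junctions(al[al$read_id == "u1", ])), 0)
})

test_that("union-mode counting assigns, discards ambiguous and tallies a partition", {
  genome <- overlapping_genome()  # gene A [100,500), gene B [400,900)
  al <- tibble::tribble(
    ~read_id, ~chrom, ~start, ~end,
    "inA1", "chr1", 150, 250,
    "inA2", "chr1", 200, 300,
    "inB1", "chr1", 600, 700,
    "both", "chr1", 420, 480,   # inside A and B: ambiguous
    "none", "chr1", 1500, 1600, # intergenic
    "half", "chr1", 50, 150     # overlaps only A: assigned (any-overlap rule)
  )
  res <- count_gene_reads(al, genome)
  counts <- setNames(res$gene_counts$count, res$gene_counts$gene_id)
  expect_equal(unname(counts["A"]), 3)
  expect_equal(unname(counts["B"]), 1)
  expect_equal(res$ambiguous, 1L)
  expect_equal(res$no_feature, 1L)
  expect_equal(sum(res$gene_counts$count) + res$ambiguous + res$no_feature,
               length(unique(al$read_id)))
})

test_that("a gapped read counts for a gene only if all blocks are exonic there", {
  genome <- genome_model(
    chromosomes = tibble::tibble(name = "chr1", length = 2000,
                                 circular = FALSE, compartment = "nuclear"),
    transcripts = tibble::tibble(transcript_id = "A.t1", gene_id = "A",
                                 chrom = "chr1", strand = "+",
                                 biotype = "protein_coding"),
    exons = tibble::tibble(transcript_id = "A.t1", exon_rank = 1:2,
                           chrom = "chr1", start = c(100, 500),
                           end = c(200, 600))
  )
  al <- tibble::tribble(
    ~read_id, ~chrom, ~start, ~end,
    "spliced", "chr1", 150, 200,
    "spliced", "chr1", 500, 550,
    "intronic", "chr1", 150, 200,
    "intronic", "chr1", 300, 350  # second block in the intron
  )
  res <- count_gene_reads(al, genome)
  expect_equal(res$gene_counts$count[res$gene_counts$gene_id == "A"], 1)
  expect_equal(res$no_feature, 1L)
})

test_that("sample totals recover the simulator's composition", {
  cfg <- small_config(reads = 4000, seed = 17)
  genome <- build_toy_genome(cfg)
  smp <- simulate_sample(genome, cfg, "con", 1)
  tot <- sample_totals(smp$alignments, genome, smp$sample_id)
  expect_equal(tot$total_reads, cfg$reads_per_sample)
  expect_equal(tot$gapped_reads + tot$ungapped_reads, tot$total_reads)
  expect_lte(tot$mito_ungapped_reads, tot$ungapped_reads)
  expect_equal(tot$mito_reads,
               sum(smp$truth$unit_reads$reads) + smp$truth$precursor_reads)
  expect_equal(sum(tot$gene_counts$count) + tot$no_feature + tot$ambiguous,
               tot$total_reads)
})

test_that("SAM round trip reproduces simulated blocks and counts exactly", {
  cfg <- sim_config(reads_per_sample = 3000,
                    precursor_fraction = c(con = 0, ldl = 0), seed = 23)
  genome <- build_toy_genome(cfg)
  smp <- simulate_sample(genome, cfg, "ldl", 1)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "s.sam")
  write_sam(smp$alignments, genome, sam)
  back <- read_alignments(sam)
  a <- dplyr::arrange(smp$alignments, read_id, start)
  b <- dplyr::arrange(back, read_id, start)
  expect_equal(a$read_id, b$read_id)
  expect_equal(a$chrom, b$chrom)
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)

  # parsed junction counts equal the simulator's truth
  jc <- count_junctions(back)
  tr <- smp$truth$junction_reads
  m <- dplyr::full_join(jc, tr, by = c("chrom", "donor_end", "acceptor_start"))
  m$count[is.na(m$count)] <- 0
  expect_equal(m$count, m$reads)

  # parsed per-gene counts equal the truth (no precursor => no ambiguity)
  tot <- sample_totals(back, genome, "ldl_1")
  counts <- setNames(tot$gene_counts$count, tot$gene_counts$gene_id)
  expect_equal(unname(counts["NUC1"]), sum(smp$truth$isoform_reads$reads))
  for (i in seq_len(nrow(smp$truth$unit_reads))) {
    expect_equal(unname(counts[smp$truth$unit_reads$gene_id[i]]),
                 smp$truth$unit_reads$reads[i])
  }
})

test_that("junction BED output is 0-based with the count as score", {
  jc <- tibble::tibble(chrom = "chr1", donor_end = 50, acceptor_start = 250,
                       count = 7L)
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "jx.bed")
  write_junction_bed(jc, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(fields[1:3], c("chr1", "50", "250"))
  expect_equal(fields[5], "7")
})
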