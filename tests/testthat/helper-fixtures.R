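# shared small fixtures, all built in code

small_config <- function(reads = 5000, seed = 101, ...) {
  sim_config(reads_per_sample = reads, seed = seed, ...)
}

# a null design: nothing differs between conditions
null_config <- function(reads = 4000, seed = 1) {
  sim_config(
    reads_per_sample = reads,
    mito_fraction = c(con = 0.05, ldl = 0.05),
    isoform_mixture = list(
      con = c(NUC1.full = 0.8, NUC1.short = 0.2),
      ldl = c(NUC1.full = 0.8, NUC1.short = 0.2)
    ),
    precursor_fraction = c(con = 0.05, ldl = 0.05),
    seed = seed
  )
}

fake_totals <- function(sample_id = "s1", total = 10000, gapped = 1000,
                        mito = 500, mito_ungapped = 450,
                        gene_counts = tibble::tibble(gene_id = "NUC1",
                                                     count = 200)) {
  structure(
    list(
      sample_id = sample_id, total_reads = total, gapped_reads = gapped,
      ungapped_reads = total - gapped, mito_reads = mito,
      mito_ungapped_reads = mito_ungapped, gene_counts = gene_counts,
      no_feature = 0L, ambiguous = 0L
    ),
    class = "sample_totals"
  )
}

# a two-gene annotation whose genes overlap, to exercise ambiguous reads
overlapping_genome <- function() {
  genome_model(
    chromosomes = tibble::tibble(name = "chr1", length = 2000,
                                 circular = FALSE, compartment = "nuclear"),
    transcripts = tibble::tibble(
      transcript_id = c("A.t1", "B.t1"),
      gene_id = c("A", "B"), chrom = "chr1", strand = "+",
      biotype = "protein_coding"
    ),
    exons = tibble::tibble(
      transcript_id = c("A.t1", "B.t1"),
      exon_rank = 1L, chrom = "chr1",
      start = c(100, 400), end = c(500, 900)
    )
  )
}

blocks_tbl <- function(...) {
  tibble::tribble(...)
}
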