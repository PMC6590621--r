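# ---- parsing alignments into the shared blocks representation --------------
#
# An aligned single-end read is an ordered set of genomic blocks (0-based
# half-open).  CIGAR skip operations (N) split blocks; deletions (D) stay
# inside a block; insertions and soft clips consume query only.  A read is
# "gapped" iff it has >= 2 blocks, i.e. it is an exon-exon junction read.

#' Read single-end alignments from SAM or BAM
#'
#' Unmapped, secondary and supplementary records are skipped.  SAM input is
#' converted to BAM on the fly via Rsamtools.
#'
#' @param path SAM or BAM file.
#' @return Blocks tibble: `read_id`, `chrom`, `start`, `end` (0-based
#'   half-open), one row per block, rows of one read consecutive and
#'   sorted by `start`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE
  )
  ga <- GenomicAlignments::readGAlignments(
    path, use.names = TRUE,
    param = Rsamtools::ScanBamParam(flag = flags)
  )
  grl <- GenomicAlignments::grglist(ga, drop.D.ranges = FALSE)
  flat <- unlist(grl, use.names = FALSE)
  tibble::tibble(
    read_id = rep(names(ga), S4Vectors::elementNROWS(grl)),
    chrom = as.character(GenomicRanges::seqnames(flat)),
    start = GenomicRanges::start(flat) - 1,
    end = as.numeric(GenomicRanges::end(flat))
  )
}

#' Classify reads as gapped or ungapped
#'
#' @param alignments Blocks tibble (see [read_alignments()]).
#' @return Tibble `read_id`, `n_blocks`, `gapped` (TRUE iff >= 2 blocks).
#' @export
classify_reads <- function(alignments) {
  ids <- unique(alignments$read_id)
  nb <- tabulate(match(alignments$read_id, ids), nbins = length(ids))
  tibble::tibble(read_id = ids, n_blocks = nb, gapped = nb >= 2L)
}

#' Extract exon-exon junctions from gapped reads
#'
#' One junction per adjacent block pair: the donor is the (exclusive) end
#' of the upstream block, the acceptor the start of the downstream block.
#' Ungapped reads contribute nothing.
#'
#' @param alignments Blocks tibble.
#' @return Tibble `read_id`, `chrom`, `donor_end`, `acceptor_start`.
#' @export
extract_junctions <- function(alignments) {
  al <- arrange(alignments, read_id, start)
  n <- nrow(al)
  if (n < 2) {
    return(tibble::tibble(read_id = character(0), chrom = character(0),
                          donor_end = numeric(0), acceptor_start = numeric(0)))
  }
  # adjacent block pairs belong to the same junction iff they share a read
  adjacent <- al$read_id[-1] == al$read_id[-n]
  tibble::tibble(
    read_id = al$read_id[-n][adjacent],
    chrom = al$chrom[-n][adjacent],
    donor_end = al$end[-n][adjacent],
    acceptor_start = al$start[-1][adjacent]
  )
}

#' Count reads per junction
#'
#' @param alignments Blocks tibble.
#' @return Tibble `chrom`, `donor_end`, `acceptor_start`, `count`.
#' @export
count_junctions <- function(alignments) {
  extract_junctions(alignments) %>%
    count(chrom, donor_end, acceptor_start, name = "count")
}

# per-gene reduced exonic GRanges + parallel gene id vector
gene_exon_ranges <- function(genome) {
  ex <- genome$exons %>%
    left_join(select(genome$transcripts, transcript_id, gene_id),
              by = "transcript_id")
  gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(start = ex$start + 1L, end = ex$end)
  )
  grl <- GenomicRanges::reduce(S4Vectors::split(gr, ex$gene_id))
  flat <- unlist(grl, use.names = FALSE)
  list(ranges = flat, gene_id = rep(names(grl), S4Vectors::elementNROWS(grl)))
}

#' Union-mode gene-level read counting
#'
#' A read is assigned to a gene only if every one of its blocks overlaps
#' that gene's exons and no block overlaps any other gene.  Reads touching
#' no gene are tallied as `no_feature`; reads touching more than one gene
#' (or only partially covered by their single gene) as `ambiguous` /
#' `no_feature` respectively, and excluded from gene counts.
#'
#' @param alignments Blocks tibble.
#' @param genome A [genome_model()].
#' @return List: `gene_counts` (tibble `gene_id`, `count`, zero rows kept
#'   for unexpressed genes), `no_feature`, `ambiguous`.
#' @export
count_gene_reads <- function(alignments, genome) {
  genes <- sort(unique(genome$transcripts$gene_id))
  zero <- tibble::tibble(gene_id = genes, count = 0)
  if (nrow(alignments) == 0) {
    return(list(gene_counts = zero, no_feature = 0L, ambiguous = 0L))
  }
  gx <- gene_exon_ranges(genome)
  bl <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(start = alignments$start + 1, end = alignments$end)
  )
  hits <- GenomicRanges::findOverlaps(bl, gx$ranges)
  # integer-indexed (read, block, gene) hit triples, de-duplicated
  read_ids <- unique(alignments$read_id)
  ridx <- match(alignments$read_id, read_ids)
  genes_hit <- sort(unique(gx$gene_id))
  K <- length(genes_hit)
  q <- S4Vectors::queryHits(hits)
  g_of_hit <- match(gx$gene_id[S4Vectors::subjectHits(hits)], genes_hit)
  # de-duplicate (block, gene) pairs with a numeric key (block implies read)
  bg_key <- q * (K + 1) + g_of_hit
  keep_bg <- !duplicated(bg_key)
  hb <- list(read = ridx[q[keep_bg]], block = q[keep_bg],
             gene = g_of_hit[keep_bg])
  n_blocks_per_read <- tabulate(ridx, nbins = length(read_ids))

  rg_key <- hb$read * (K + 1) + hb$gene
  keep_rg <- !duplicated(rg_key)
  n_genes_per_read <- tabulate(hb$read[keep_rg], nbins = length(read_ids))
  # distinct blocks of each (read, gene) couple
  key <- (hb$read - 1) * (K + 1) + hb$gene
  ukey <- sort(unique(key))
  hit_blocks <- tabulate(match(key, ukey), nbins = length(ukey))
  key_read <- (ukey - 1) %/% (K + 1) + 1
  key_gene <- (ukey - 1) %% (K + 1) + 1

  single <- n_genes_per_read == 1
  covered <- rep(FALSE, length(read_ids))
  covered[key_read[hit_blocks == n_blocks_per_read[key_read]]] <- TRUE
  assigned_read <- single & covered
  ambiguous <- sum(n_genes_per_read > 1)
  no_feature <- sum(n_genes_per_read == 0) + sum(single & !covered)

  keep <- assigned_read[key_read]
  counts <- tibble::tibble(gene_id = genes_hit[key_gene[keep]]) %>%
    count(gene_id, name = "count")
  gene_counts <- zero %>%
    left_join(counts, by = "gene_id", suffix = c(".z", "")) %>%
    mutate(count = ifelse(is.na(count), 0, count)) %>%
    select(gene_id, count)
  list(gene_counts = gene_counts, no_feature = as.integer(no_feature),
       ambiguous = as.integer(ambiguous))
}

#' Per-sample read tallies
#'
#' Totals feeding every downstream normalization: total/gapped/ungapped
#' reads, reads on the mitochondrial compartment (all and ungapped only),
#' and union-mode per-gene counts.
#'
#' @param alignments Blocks tibble for one sample.
#' @param genome A [genome_model()].
#' @param sample_id Sample label carried into the result.
#' @param gene_counts Set `FALSE` to skip union-mode gene counting when
#'   only the read tallies are needed (the `gene_counts` field is then an
#'   empty tibble).
#' @return A list of class `sample_totals` with fields `sample_id`,
#'   `total_reads`, `gapped_reads`, `ungapped_reads`, `mito_reads`,
#'   `mito_ungapped_reads`, `gene_counts`, `no_feature`, `ambiguous`.
#' @export
sample_totals <- function(alignments, genome, sample_id = NA_character_,
                          gene_counts = TRUE) {
  cls <- classify_reads(alignments)
  mito_chroms <- genome$chromosomes$name[genome$chromosomes$compartment == "mito"]
  mito_ids <- unique(alignments$read_id[alignments$chrom %in% mito_chroms])
  gc <- if (gene_counts) {
    count_gene_reads(alignments, genome)
  } else {
    list(gene_counts = tibble::tibble(gene_id = character(0),
                                      count = numeric(0)),
         no_feature = NA_integer_, ambiguous = NA_integer_)
  }
  structure(
    list(
      sample_id = sample_id,
      total_reads = nrow(cls),
      gapped_reads = sum(cls$gapped),
      ungapped_reads = sum(!cls$gapped),
      mito_reads = length(unique(mito_ids)),
      mito_ungapped_reads = sum(!cls$gapped & cls$read_id %in% mito_ids),
      gene_counts = gc$gene_counts,
      no_feature = gc$no_feature,
      ambiguous = gc$ambiguous
    ),
    class = "sample_totals"
  )
}

#' @export
print.sample_totals <- function(x, ...) {
  cat("<sample_totals> ", x$sample_id, ": ", x$total_reads, " reads (",
      x$gapped_reads, " gapped, ", x$mito_reads, " mitochondrial)\n", sep = "")
  invisible(x)
}

#' Write junction counts as BED
#'
#' One record per junction (0-based, thick interval from donor to
#' acceptor), count in the score column.
#'
#' @param junction_counts Output of [count_junctions()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junction_counts, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t+",
                   junction_counts$chrom,
                   as.integer(junction_counts$donor_end),
                   as.integer(junction_counts$acceptor_start),
                   sprintf("jx_%s_%d_%d", junction_counts$chrom,
                           as.integer(junction_counts$donor_end),
                           as.integer(junction_counts$acceptor_start)),
                   as.integer(junction_counts$count))
  writeLines(lines, path)
  invisible(path)
}
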