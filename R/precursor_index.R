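# ---- mitochondrial precursor-transcript border-coverage index ---------------
#
# The mitochondrial genome is transcribed as long polycistronic precursors
# that are cleaved into mature units (tRNA punctuation).  An ungapped read
# that covers the border between two neighboring units by at least
# `min_overlap` nucleotides on each side can only come from an unprocessed
# precursor, so the normalized average of such border-spanning coverage
# approximates the relative precursor abundance in a sample.

#' Enumerate neighboring mitochondrial transcript borders
#'
#' Mitochondrial transcript units are sorted by genomic start; one border
#' pair is produced per adjacent couple.  The pair across the circular
#' origin (last unit, first unit) is excluded unless `include_origin` is
#' set, because linear alignments cannot span it.
#'
#' @param genome A [genome_model()] whose mito chromosome carries >= 2
#'   single-exon transcript units.
#' @param include_origin Add the (last, first) origin-wrapping pair.
#' @return Tibble `upstream_id`, `downstream_id`, `upstream_end`,
#'   `downstream_start` (0-based; `downstream_start >= upstream_end`).
#' @export
enumerate_border_pairs <- function(genome, include_origin = FALSE) {
  units <- mito_units(genome)
  if (nrow(units) < 2) {
    return(tibble::tibble(chrom = character(0),
                          upstream_id = character(0),
                          downstream_id = character(0),
                          upstream_end = numeric(0),
                          downstream_start = numeric(0)))
  }
  overlap <- which(units$start[-1] < units$end[-nrow(units)])
  if (length(overlap)) {
    stop("overlapping mitochondrial transcripts: ",
         paste(sprintf("%s/%s", units$transcript_id[overlap],
                       units$transcript_id[overlap + 1]), collapse = ", "))
  }
  n <- nrow(units)
  pairs <- tibble::tibble(
    chrom = units$chrom[-n],
    upstream_id = units$transcript_id[-n],
    downstream_id = units$transcript_id[-1],
    upstream_end = units$end[-n],
    downstream_start = units$start[-1]
  )
  if (include_origin) {
    pairs <- bind_rows(pairs, tibble::tibble(
      chrom = units$chrom[n],
      upstream_id = units$transcript_id[n],
      downstream_id = units$transcript_id[1],
      upstream_end = units$end[n],
      downstream_start = units$start[1]
    ))
  }
  pairs
}

#' Count ungapped reads spanning transcript borders
#'
#' A single-block read `[a, b)` spans the border pair iff it overlaps the
#' upstream unit's terminal region by `upstream_end - a >= min_overlap` and
#' the downstream unit's initial region by `b - downstream_start >=
#' min_overlap`.  For near-abutting neighbors each condition applies to its
#' own coordinate; a read lying entirely inside the gap counts for
#' neither.  Gapped reads are excluded a priori (spliced reads are mature
#' by definition).  A read spanning a very short intervening unit entirely
#' can satisfy two pairs and is counted for each.
#'
#' @param alignments Blocks tibble for one sample.
#' @param pairs Output of [enumerate_border_pairs()].
#' @param min_overlap Minimal overlap on each side, in nt (default 6).
#' @return `pairs` with an added `count` column.
#' @export
count_border_spanning <- function(alignments, pairs, min_overlap = 6) {
  stopifnot(min_overlap >= 1)
  cls <- classify_reads(alignments)
  ungapped <- alignments %>%
    filter(read_id %in% cls$read_id[!cls$gapped])
  pairs$count <- vapply(seq_len(nrow(pairs)), function(i) {
    on_chrom <- ungapped$chrom == pairs$chrom[i]
    sum(on_chrom &
          pairs$upstream_end[i] - ungapped$start >= min_overlap &
          ungapped$end - pairs$downstream_start[i] >= min_overlap)
  }, numeric(1))
  pairs
}

#' Normalize border coverage and average it into the precursor index
#'
#' Each raw border count is normalized to the sample's total number of
#' ungapped reads and to the fraction of ungapped reads mapping to the
#' mitochondrial genome:
#' `norm = scale * count / (ungapped * mito_ungapped/ungapped)`.
#' The per-sample precursor index is the arithmetic mean over border
#' pairs.
#'
#' @param border_counts Output of [count_border_spanning()].
#' @param totals A [sample_totals()] for the same sample.
#' @param scale Readability scale factor (default 1e6).
#' @return List: `pairs` (border_counts with `norm_coverage`),
#'   `mean_index`, `sample_id`.
#' @export
normalize_border_coverage <- function(border_counts, totals, scale = 1e6) {
  stopifnot(inherits(totals, "sample_totals"))
  if (totals$ungapped_reads <= 0) {
    stop("normalize_border_coverage(): no ungapped reads in sample")
  }
  m <- totals$mito_ungapped_reads / totals$ungapped_reads
  if (m == 0) {
    if (any(border_counts$count > 0)) {
      stop("border-spanning reads found but no mitochondrial ungapped reads; ",
           "inconsistent totals")
    }
    border_counts$norm_coverage <- 0
    return(list(pairs = border_counts, mean_index = 0,
                sample_id = totals$sample_id))
  }
  border_counts$norm_coverage <-
    scale * border_counts$count / (totals$ungapped_reads * m)
  list(pairs = border_counts,
       mean_index = mean(border_counts$norm_coverage),
       sample_id = totals$sample_id)
}

#' Compare precursor indices between conditions
#'
#' @param index_table Tibble `sample_id`, `mean_index`.
#' @param conditions Tibble `sample_id`, `condition` (two conditions,
#'   >= 2 samples each; first level is the reference).
#' @return One-row tibble `condition_a`, `condition_b`, `mean_a`, `mean_b`,
#'   `t`, `df`, `p`, `degenerate`.
#' @export
compare_precursor <- function(index_table, conditions) {
  conditions <- tibble::as_tibble(conditions)[, c("sample_id", "condition")]
  levels <- unique(conditions$condition)
  if (length(levels) != 2) stop("exactly two conditions are required")
  dat <- index_table %>% inner_join(conditions, by = "sample_id")
  a <- dat$mean_index[dat$condition == levels[1]]
  b <- dat$mean_index[dat$condition == levels[2]]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 samples per condition")
  tt <- t_test_unpaired(a, b)
  tibble::tibble(
    condition_a = levels[1], condition_b = levels[2],
    mean_a = tt$mean_a, mean_b = tt$mean_b,
    t = tt$t, df = tt$df, p = tt$p, degenerate = tt$degenerate
  )
}

#' End-to-end precursor-index analysis of a simulated experiment
#'
#' @param experiment A [simulate_experiment()] result.
#' @param min_overlap Minimal border overlap in nt (default 6).
#' @param scale Normalization scale factor (default 1e6).
#' @return List: `per_pair` (per-sample normalized border coverages),
#'   `index` (tibble `sample_id`, `mean_index`), `comparison`.
#' @export
precursor_analysis <- function(experiment, min_overlap = 6, scale = 1e6) {
  stopifnot(inherits(experiment, "sim_experiment"))
  genome <- experiment$genome
  pairs <- enumerate_border_pairs(genome)
  per_pair <- list()
  index <- list()
  for (smp in experiment$samples) {
    totals <- sample_totals(smp$alignments, genome, smp$sample_id,
                            gene_counts = FALSE)
    bc <- count_border_spanning(smp$alignments, pairs,
                                min_overlap = min_overlap)
    nb <- normalize_border_coverage(bc, totals, scale = scale)
    per_pair[[smp$sample_id]] <- mutate(nb$pairs, sample_id = smp$sample_id)
    index[[smp$sample_id]] <- tibble::tibble(sample_id = smp$sample_id,
                                             mean_index = nb$mean_index)
  }
  index <- bind_rows(index)
  list(per_pair = bind_rows(per_pair), index = index,
       comparison = compare_precursor(index, experiment$manifest))
}
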