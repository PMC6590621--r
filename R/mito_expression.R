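# ---- nuclear/mitochondrial partition and mito gene expression ---------------

#' Nuclear vs mitochondrial read percentages
#'
#' @param totals_list List of [sample_totals()] (one per sample).
#' @return Tibble `sample_id`, `nuclear_pct`, `mito_pct`, `total_reads`;
#'   the two percentages sum to 100 exactly.
#' @export
compartment_fractions <- function(totals_list) {
  if (inherits(totals_list, "sample_totals")) totals_list <- list(totals_list)
  rows <- lapply(totals_list, function(tt) {
    stopifnot(inherits(tt, "sample_totals"))
    if (tt$total_reads <= 0) {
      stop("compartment_fractions(): sample ", tt$sample_id, " has no reads")
    }
    mito_pct <- 100 * tt$mito_reads / tt$total_reads
    tibble::tibble(
      sample_id = tt$sample_id,
      nuclear_pct = 100 - mito_pct,
      mito_pct = mito_pct,
      total_reads = tt$total_reads
    )
  })
  bind_rows(rows)
}

#' Counts per million mapped reads
#'
#' A deliberately simple library-size normalization (CPM); it is the
#' surrogate used here in place of model-based size factors.
#'
#' @param gene_counts Tibble `sample_id`, `gene_id`, `count` (long format).
#' @param totals Tibble `sample_id`, `total_reads` or a list of
#'   [sample_totals()].
#' @return `gene_counts` with an added `cpm` column.
#' @export
normalize_counts <- function(gene_counts, totals) {
  if (!is.data.frame(totals)) {
    if (inherits(totals, "sample_totals")) totals <- list(totals)
    totals <- bind_rows(lapply(totals, function(tt) {
      tibble::tibble(sample_id = tt$sample_id, total_reads = tt$total_reads)
    }))
  }
  if (any(totals$total_reads <= 0)) stop("zero total mapped reads")
  gene_counts %>%
    inner_join(totals[, c("sample_id", "total_reads")], by = "sample_id") %>%
    mutate(cpm = 1e6 * count / total_reads) %>%
    select(-total_reads)
}

#' Per-gene expression change between conditions
#'
#' log2 fold change of mean CPM (with a pseudocount keeping it finite),
#' an unpaired t-test on log2(CPM + pseudocount), and Benjamini-Hochberg
#' adjustment across the gene set.  This is a simple surrogate for a
#' negative-binomial differential-expression model, and is labelled as
#' such in the output (`method` column).
#'
#' @param cpm_table Output of [normalize_counts()].
#' @param conditions Tibble `sample_id`, `condition` (two conditions, >= 2
#'   samples each); the first condition level is the reference.
#' @param pseudocount CPM pseudocount (default 0.5).
#' @return Tibble `gene_id`, `mean_cpm_a`, `mean_cpm_b`, `l2fc`, `t`, `p`,
#'   `adjusted_p`, `method`, ordered by `p`.
#' @export
gene_change <- function(cpm_table, conditions, pseudocount = 0.5) {
  conditions <- tibble::as_tibble(conditions)[, c("sample_id", "condition")]
  levels <- unique(conditions$condition)
  if (length(levels) != 2) stop("exactly two conditions are required")
  dat <- cpm_table %>% inner_join(conditions, by = "sample_id")
  res <- lapply(split(dat, dat$gene_id), function(d) {
    a <- d$cpm[d$condition == levels[1]]
    b <- d$cpm[d$condition == levels[2]]
    if (length(a) < 2 || length(b) < 2) {
      stop("need >= 2 samples per condition for gene ", d$gene_id[1])
    }
    tt <- t_test_unpaired(log2(a + pseudocount), log2(b + pseudocount))
    tibble::tibble(
      gene_id = d$gene_id[1],
      mean_cpm_a = mean(a), mean_cpm_b = mean(b),
      l2fc = log2((mean(b) + pseudocount) / (mean(a) + pseudocount)),
      t = tt$t, p = tt$p
    )
  })
  out <- bind_rows(res)
  out$adjusted_p <- bh_adjust(out$p)
  out$method <- "t_log2cpm"
  out %>% arrange(p)
}

#' Compartment profile and mitochondrial gene changes of an experiment
#'
#' @param experiment A [simulate_experiment()] result.
#' @param pseudocount Passed to [gene_change()].
#' @return List: `totals` (per-sample [sample_totals()]), `profile`
#'   (Table-2-style compartment percentages), `mito_gene_change`
#'   ([gene_change()] restricted to mitochondrial genes).
#' @export
mito_profile <- function(experiment, pseudocount = 0.5) {
  stopifnot(inherits(experiment, "sim_experiment"))
  genome <- experiment$genome
  totals <- lapply(experiment$samples, function(smp) {
    sample_totals(smp$alignments, genome, smp$sample_id)
  })
  profile <- compartment_fractions(totals)
  counts <- bind_rows(lapply(totals, function(tt) {
    mutate(tt$gene_counts, sample_id = tt$sample_id)
  }))
  cpm <- normalize_counts(counts, totals)
  mito_genes <- gene_spans(genome) %>% filter(compartment == "mito") %>%
    pull(gene_id)
  changes <- gene_change(cpm %>% filter(gene_id %in% mito_genes),
                         experiment$manifest, pseudocount = pseudocount)
  list(totals = totals, profile = profile, mito_gene_change = changes)
}
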