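# ---- gene-normalized splice-site usage (GNSSR) ------------------------------
#
# GNSSR(j, s) = [c(j,s) / G(s)] / [g(gene,s) / T(s)]
# where c is the junction read count, G the sample's total gapped reads,
# g the union-mode read count of the junction's host gene, and T the
# sample's total mapped reads.  The statistic is a ratio of ratios:
# junction usage relative to overall splicing activity, corrected for the
# host gene's expression level.  Doubling every count leaves it unchanged.

#' Compute GNSSR records for one sample
#'
#' Each junction is attributed to the gene whose genomic span contains both
#' its donor and acceptor coordinates; junctions matching no gene or more
#' than one gene are flagged `unassigned`, and junctions of genes with a
#' zero read count are flagged `no_gene_expression`.  Flagged records carry
#' `NA` GNSSR and are excluded from group aggregation.
#'
#' @param junction_counts Tibble `chrom`, `donor_end`, `acceptor_start`,
#'   `count` (see [count_junctions()]).
#' @param totals A [sample_totals()] for the same sample
#'   (`gapped_reads > 0`).
#' @param genome A [genome_model()].
#' @param scale Optional output scale factor (default 1; magnitudes are
#'   arbitrary, only ratios between samples are meaningful).
#' @return Tibble `sample_id`, `gene_id`, `chrom`, `donor_end`,
#'   `acceptor_start`, `raw_count`, `gnssr`, `flag`.
#' @export
compute_gnssr <- function(junction_counts, totals, genome, scale = 1) {
  stopifnot(inherits(totals, "sample_totals"))
  if (totals$gapped_reads <= 0) {
    stop("compute_gnssr(): sample has no gapped reads")
  }
  spans <- gene_spans(genome)
  jc <- junction_counts
  gene_of <- vapply(seq_len(nrow(jc)), function(i) {
    hit <- spans$gene_id[
      spans$chrom == jc$chrom[i] &
        spans$start <= jc$donor_end[i] & jc$donor_end[i] <= spans$end &
        spans$start <= jc$acceptor_start[i] & jc$acceptor_start[i] < spans$end
    ]
    if (length(hit) == 1) hit else NA_character_
  }, character(1))
  counts <- stats::setNames(totals$gene_counts$count, totals$gene_counts$gene_id)
  g <- unname(counts[gene_of])
  gnssr <- scale * (jc$count / totals$gapped_reads) /
    (g / totals$total_reads)
  flag <- dplyr::case_when(
    is.na(gene_of) ~ "unassigned",
    g == 0 ~ "no_gene_expression",
    TRUE ~ "ok"
  )
  tibble::tibble(
    sample_id = totals$sample_id,
    gene_id = gene_of,
    chrom = jc$chrom,
    donor_end = jc$donor_end,
    acceptor_start = jc$acceptor_start,
    raw_count = jc$count,
    gnssr = ifelse(flag == "ok", gnssr, NA_real_),
    flag = flag
  )
}

junction_key <- function(x) {
  sprintf("%s:%d-%d", x$chrom, as.integer(x$donor_end),
          as.integer(x$acceptor_start))
}

#' Define a junction group
#'
#' A group is either an explicit set of junctions (`keys`, as
#' `"chrom:donor-acceptor"` strings) or a half-line of donor coordinates
#' (`donor_end_lt` / `donor_end_ge`), which mirrors splitting a gene's
#' junctions into those upstream and downstream of an anchor exon.
#'
#' @param name Group label.
#' @param keys Character vector of junction keys, or `NULL`.
#' @param donor_end_lt,donor_end_ge Coordinate bounds selecting junctions
#'   by donor end (0-based exclusive end of the upstream exon).
#' @param chrom Restrict coordinate rules to one chromosome (optional).
#' @return An object of class `junction_group`.
#' @export
junction_group <- function(name, keys = NULL, donor_end_lt = NULL,
                           donor_end_ge = NULL, chrom = NULL) {
  if (is.null(keys) && is.null(donor_end_lt) && is.null(donor_end_ge)) {
    stop("junction_group needs keys or a donor_end bound")
  }
  structure(
    list(name = name, keys = keys, donor_end_lt = donor_end_lt,
         donor_end_ge = donor_end_ge, chrom = chrom),
    class = "junction_group"
  )
}

#' Upstream/downstream junction groups at the toy genome's anchor exon
#'
#' @param genome A [build_toy_genome()] result (carries the anchor
#'   coordinate as an attribute).
#' @return List of two [junction_group()]s named `upstream`, `downstream`.
#' @export
anchor_junction_groups <- function(genome) {
  anchor <- attr(genome, "anchor")
  if (is.null(anchor)) stop("genome carries no anchor attribute")
  list(
    junction_group("upstream", donor_end_lt = anchor$split_coord),
    junction_group("downstream", donor_end_ge = anchor$split_coord)
  )
}

#' Read junction-group definitions from YAML
#'
#' The file is a list of groups, each with a `name` and either `junctions`
#' (list of `chrom`/`donor_end`/`acceptor_start` triples) or
#' `donor_end_lt`/`donor_end_ge` (with optional `chrom`).
#'
#' @param path YAML file.
#' @return List of [junction_group()]s.
#' @export
read_junction_groups <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(g) {
    keys <- NULL
    if (!is.null(g$junctions)) {
      keys <- vapply(g$junctions, function(j) {
        sprintf("%s:%d-%d", j$chrom, as.integer(j$donor_end),
                as.integer(j$acceptor_start))
      }, character(1))
    }
    junction_group(g$name, keys = keys, donor_end_lt = g$donor_end_lt,
                   donor_end_ge = g$donor_end_ge, chrom = g$chrom)
  })
}

group_members <- function(group, universe) {
  sel <- rep(TRUE, nrow(universe))
  if (!is.null(group$chrom)) sel <- sel & universe$chrom == group$chrom
  if (!is.null(group$keys)) sel <- sel & junction_key(universe) %in% group$keys
  if (!is.null(group$donor_end_lt)) {
    sel <- sel & universe$donor_end < group$donor_end_lt
  }
  if (!is.null(group$donor_end_ge)) {
    sel <- sel & universe$donor_end >= group$donor_end_ge
  }
  universe[sel, , drop = FALSE]
}

#' Per-sample mean GNSSR of a junction group
#'
#' The junction universe is the set of junctions observed (with an
#' assignable GNSSR) in at least one sample of the experiment; junctions
#' unobserved in a particular sample contribute 0 to that sample's mean,
#' junctions observed nowhere are excluded entirely.
#'
#' @param records Row-bound [compute_gnssr()] output across all samples.
#' @param group A [junction_group()].
#' @return Tibble `sample_id`, `group`, `mean_gnssr`.
#' @export
aggregate_group <- function(records, group) {
  ok <- records %>% filter(flag == "ok")
  universe <- ok %>% distinct(chrom, donor_end, acceptor_start)
  members <- group_members(group, universe)
  if (nrow(members) == 0) {
    stop("junction group '", group$name, "' has an empty universe")
  }
  samples <- unique(records$sample_id)
  grid <- tidyr_grid(samples, members)
  grid %>%
    left_join(ok, by = c("sample_id", "chrom", "donor_end", "acceptor_start")) %>%
    mutate(gnssr = ifelse(is.na(gnssr), 0, gnssr)) %>%
    group_by(sample_id) %>%
    summarise(mean_gnssr = mean(gnssr), .groups = "drop") %>%
    mutate(group = group$name) %>%
    select(sample_id, group, mean_gnssr)
}

tidyr_grid <- function(samples, members) {
  idx <- rep(seq_len(nrow(members)), times = length(samples))
  tibble::tibble(
    sample_id = rep(samples, each = nrow(members)),
    chrom = members$chrom[idx],
    donor_end = members$donor_end[idx],
    acceptor_start = members$acceptor_start[idx]
  )
}

#' Aggregate several junction groups
#'
#' @param records Row-bound [compute_gnssr()] output.
#' @param groups List of [junction_group()]s.
#' @return Tibble `sample_id`, `group`, `mean_gnssr`.
#' @export
aggregate_groups <- function(records, groups) {
  bind_rows(lapply(groups, function(g) aggregate_group(records, g)))
}

#' Compare junction-group usage between conditions
#'
#' Unpaired two-sided Student's t-test on the per-sample group means; the
#' first condition level is treated as reference ("a").
#'
#' @param group_means Output of [aggregate_groups()].
#' @param conditions Tibble `sample_id`, `condition` (e.g. a simulation
#'   manifest); needs >= 2 samples per condition and exactly 2 conditions.
#' @return Tibble `group`, `condition_a`, `condition_b`, `mean_a`,
#'   `mean_b`, `t`, `df`, `p`, `degenerate`.
#' @export
compare_junction_groups <- function(group_means, conditions) {
  conditions <- tibble::as_tibble(conditions)[, c("sample_id", "condition")]
  levels <- unique(conditions$condition)
  if (length(levels) != 2) stop("exactly two conditions are required")
  dat <- group_means %>% inner_join(conditions, by = "sample_id")
  res <- lapply(split(dat, dat$group), function(d) {
    a <- d$mean_gnssr[d$condition == levels[1]]
    b <- d$mean_gnssr[d$condition == levels[2]]
    if (length(a) < 2 || length(b) < 2) {
      stop("need >= 2 samples per condition in group ", d$group[1])
    }
    tt <- t_test_unpaired(a, b)
    tibble::tibble(
      group = d$group[1], condition_a = levels[1], condition_b = levels[2],
      mean_a = tt$mean_a, mean_b = tt$mean_b, t = tt$t, df = tt$df,
      p = tt$p, degenerate = tt$degenerate
    )
  })
  bind_rows(res)
}

#' End-to-end GNSSR analysis of a simulated experiment
#'
#' Counts junctions, computes per-sample totals and GNSSR records,
#' aggregates the requested junction groups and compares them between the
#' two conditions.
#'
#' @param experiment A [simulate_experiment()] result.
#' @param groups List of [junction_group()]s; defaults to the toy genome's
#'   upstream/downstream split at the anchor exon.
#' @param scale GNSSR scale factor (see [compute_gnssr()]).
#' @return List: `records`, `group_means`, `comparison`.
#' @export
gnssr_analysis <- function(experiment, groups = NULL, scale = 1) {
  stopifnot(inherits(experiment, "sim_experiment"))
  if (is.null(groups)) groups <- anchor_junction_groups(experiment$genome)
  records <- bind_rows(lapply(experiment$samples, function(smp) {
    totals <- sample_totals(smp$alignments, experiment$genome, smp$sample_id)
    compute_gnssr(count_junctions(smp$alignments), totals,
                  experiment$genome, scale = scale)
  }))
  group_means <- aggregate_groups(records, groups)
  comparison <- compare_junction_groups(group_means, experiment$manifest)
  list(records = records, group_means = group_means, comparison = comparison)
}
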