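# ---- synthetic aligned-read simulator ---------------------------------------
#
# Reads are drawn hierarchically: compartment ~ Bernoulli(mito_fraction);
# nuclear reads pick an isoform from the condition's mixture and a uniform
# start on the spliced transcript, and their genomic blocks are obtained by
# projecting the spliced interval through the exon map (gapped iff the read
# spans a junction); mitochondrial reads are either precursor reads (uniform
# on the contiguous transcript-unit span, may cross unit borders) or mature
# reads (one unit chosen proportional to its length, confined to that unit).
# Mature reads on units shorter than the read length are truncated to the
# unit, so mature reads can never cross a border.

# spliced-coordinate exon map for one transcript
spliced_map <- function(genome, transcript_id) {
  ex <- genome$exons[genome$exons$transcript_id == transcript_id, ]
  ex <- ex[order(ex$start), ]
  len <- ex$end - ex$start
  tibble::tibble(
    chrom = ex$chrom,
    genomic_start = ex$start,
    exon_length = len,
    spliced_offset = cumsum(c(0, len[-length(len)]))
  )
}

# project spliced intervals [s, s + width) through an exon map into genomic
# blocks; returns a tibble (read, chrom, start, end) with one row per block
project_spliced <- function(map, starts, width) {
  n_reads <- length(starts)
  k <- nrow(map)
  if (n_reads == 0) {
    return(tibble::tibble(read = integer(0), chrom = character(0),
                          start = numeric(0), end = numeric(0)))
  }
  read <- rep(seq_len(n_reads), each = k)
  s <- rep(starts, each = k)
  off <- rep(map$spliced_offset, times = n_reads)
  elen <- rep(map$exon_length, times = n_reads)
  gstart <- rep(map$genomic_start, times = n_reads)
  bs <- pmax(s, off)
  be <- pmin(s + width, off + elen)
  keep <- be > bs
  tibble::tibble(
    read = read[keep],
    chrom = map$chrom[1],
    start = gstart[keep] + (bs[keep] - off[keep]),
    end = gstart[keep] + (be[keep] - off[keep])
  )
}

# junction catalogue of one transcript: spliced coordinate plus genomic key
transcript_junctions <- function(map) {
  k <- nrow(map)
  if (k < 2) {
    return(tibble::tibble(chrom = character(0), donor_end = numeric(0),
                          acceptor_start = numeric(0), spliced = numeric(0)))
  }
  tibble::tibble(
    chrom = map$chrom[1],
    donor_end = map$genomic_start[-k] + map$exon_length[-k],
    acceptor_start = map$genomic_start[-1],
    spliced = map$spliced_offset[-1]
  )
}

#' Simulate one aligned sample
#'
#' Draws `reads_per_sample` single-end alignments for one condition and
#' replicate, together with a ground-truth table of realized counts.  The
#' RNG stream is derived deterministically from `(seed, condition,
#' replicate)`, so identical configurations reproduce identical samples.
#'
#' @param genome A [build_toy_genome()] / [genome_model()] result.
#' @param config A [sim_config()].
#' @param condition One of `config$conditions`.
#' @param replicate Replicate index in `1..n_replicates_per_condition`.
#' @return A list with elements `sample_id`, `condition`, `replicate`,
#'   `alignments` (tibble of blocks: `read_id`, `chrom`, `start`, `end`,
#'   0-based half-open) and `truth` (list of realized per-isoform,
#'   per-unit, precursor, per-junction and per-border counts).
#' @examples
#' cfg <- sim_config(reads_per_sample = 500)
#' smp <- simulate_sample(build_toy_genome(cfg), cfg, "con", 1)
#' head(smp$alignments)
#' @export
simulate_sample <- function(genome, config, condition, replicate) {
  stopifnot(inherits(config, "sim_config"),
            condition %in% config$conditions,
            replicate >= 1,
            replicate <= config$n_replicates_per_condition)
  cond_idx <- match(condition, config$conditions)
  sample_id <- sprintf("%s_%d", condition, replicate)
  n <- config$reads_per_sample
  rl <- config$read_length
  units <- mito_units(genome)
  pairs <- enumerate_border_pairs(genome)
  mix <- config$isoform_mixture[[condition]]

  sim <- withr_seed(derive_seed(config$seed, cond_idx, replicate), {
    n_mito <- rbinom(1, n, config$mito_fraction[[condition]])
    n_nuc <- n - n_mito

    # --- nuclear reads ------------------------------------------------------
    iso_counts <- if (n_nuc > 0) {
      drop(rmultinom(1, n_nuc, mix))
    } else {
      stats::setNames(rep(0L, length(mix)), names(mix))
    }
    nuc_blocks <- list()
    junction_truth <- list()
    for (iso in names(mix)) {
      m <- iso_counts[[iso]]
      map <- spliced_map(genome, iso)
      jx <- transcript_junctions(map)
      if (m == 0) {
        if (nrow(jx)) junction_truth[[iso]] <- mutate(jx, reads = 0L)
        next
      }
      L <- sum(map$exon_length)
      starts <- floor(runif(m, min = 0, max = L - rl + 1))
      nuc_blocks[[iso]] <- project_spliced(map, starts, rl)
      if (nrow(jx)) {
        jx$reads <- vapply(jx$spliced, function(cj) {
          sum(starts <= cj - 1 & starts + rl >= cj + 1)
        }, numeric(1))
        junction_truth[[iso]] <- jx
      }
    }

    # --- mitochondrial reads ------------------------------------------------
    n_pre <- if (n_mito > 0) {
      rbinom(1, n_mito, config$precursor_fraction[[condition]])
    } else 0L
    n_mat <- n_mito - n_pre
    span_start <- min(units$start)
    span_end <- max(units$end)
    pre_start <- if (n_pre > 0) {
      floor(runif(n_pre, min = span_start, max = span_end - rl + 1))
    } else numeric(0)
    unit_idx <- if (n_mat > 0) {
      sample.int(nrow(units), n_mat, replace = TRUE,
                 prob = units$end - units$start)
    } else integer(0)
    mat_len <- pmin(rl, (units$end - units$start)[unit_idx])
    mat_start <- if (n_mat > 0) {
      units$start[unit_idx] +
        floor(runif(n_mat) * ((units$end - units$start)[unit_idx] - mat_len + 1))
    } else numeric(0)

    list(iso_counts = iso_counts, junction_truth = junction_truth,
         nuc_blocks = nuc_blocks, n_pre = n_pre, pre_start = pre_start,
         unit_idx = unit_idx, mat_start = mat_start, mat_len = mat_len)
  })

  mito_chrom <- genome$chromosomes$name[genome$chromosomes$compartment == "mito"][1]
  mito_tbl <- tibble::tibble(
    read = seq_len(sim$n_pre + length(sim$unit_idx)),
    chrom = mito_chrom,
    start = c(sim$pre_start, sim$mat_start),
    end = c(sim$pre_start + rl, sim$mat_start + sim$mat_len)
  )

  # assemble one blocks table; read ids are global within the sample
  nuc <- bind_rows(sim$nuc_blocks, .id = "isoform")
  if (nrow(nuc)) {
    # reads were numbered per isoform; renumber globally
    grp <- paste(nuc$isoform, nuc$read)
    nuc_ids <- match(grp, unique(grp))
    nuc_part <- tibble::tibble(read = nuc_ids, chrom = nuc$chrom,
                               start = nuc$start, end = nuc$end)
  } else {
    nuc_ids <- integer(0)
    nuc_part <- tibble::tibble(read = integer(0), chrom = character(0),
                               start = numeric(0), end = numeric(0))
  }
  blocks <- bind_rows(
    nuc_part,
    mutate(mito_tbl, read = read + length(unique(nuc_ids)))
  )
  blocks <- blocks %>%
    mutate(read_id = sprintf("%s.r%07d", sample_id, read)) %>%
    select(read_id, chrom, start, end) %>%
    arrange(read_id, start)

  # --- ground truth ---------------------------------------------------------
  jt <- bind_rows(sim$junction_truth)
  junction_reads <- if (nrow(jt)) {
    jt %>%
      group_by(chrom, donor_end, acceptor_start) %>%
      summarise(reads = sum(reads), .groups = "drop")
  } else {
    tibble::tibble(chrom = character(0), donor_end = numeric(0),
                   acceptor_start = numeric(0), reads = numeric(0))
  }
  unit_reads <- units %>%
    select(transcript_id, gene_id) %>%
    mutate(reads = tabulate(sim$unit_idx, nbins = nrow(units)))
  border_reads <- pairs
  border_reads$reads <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(sim$pre_start <= pairs$upstream_end[i] - 6 &
          sim$pre_start + rl >= pairs$downstream_start[i] + 6)
  }, numeric(1))

  truth <- list(
    isoform_reads = tibble::tibble(
      isoform_id = names(sim$iso_counts),
      reads = as.integer(sim$iso_counts)
    ),
    unit_reads = unit_reads,
    precursor_reads = as.integer(sim$n_pre),
    junction_reads = junction_reads,
    border_reads = border_reads,
    border_min_overlap = 6L
  )
  list(sample_id = sample_id, condition = condition, replicate = replicate,
       alignments = blocks, truth = truth)
}

#' Simulate a full two-condition experiment
#'
#' Runs [simulate_sample()] for every condition and replicate in the
#' design.  With `outdir` set, writes everything a downstream run needs:
#' reference FASTA, GTF annotation, one coordinate-sorted SAM per sample, a
#' sample manifest, a long-format truth table and an echo of the
#' configuration as YAML.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created; must not already
#'   contain a manifest).
#' @return A list of class `sim_experiment`: `genome`, `samples` (list of
#'   [simulate_sample()] results), `manifest` (tibble: `sample_id`,
#'   `condition`, `replicate`, `path`), `config`.
#' @examples
#' exp <- simulate_experiment(sim_config(reads_per_sample = 200))
#' exp$manifest
#' @export
simulate_experiment <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- build_toy_genome(config)
  samples <- list()
  manifest <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    for (r in seq_len(config$n_replicates_per_condition)) {
      smp <- simulate_sample(genome, config, cond, r)
      samples[[smp$sample_id]] <- smp
      manifest[[smp$sample_id]] <- tibble::tibble(
        sample_id = smp$sample_id, condition = cond, replicate = r,
        path = if (is.null(outdir)) NA_character_ else
          file.path(outdir, paste0(smp$sample_id, ".sam"))
      )
    }
  }
  manifest <- bind_rows(manifest)
  out <- structure(
    list(genome = genome, samples = samples, manifest = manifest,
         config = config),
    class = "sim_experiment"
  )
  if (!is.null(outdir)) {
    if (file.exists(file.path(outdir, "manifest.tsv"))) {
      stop("output collision: ", file.path(outdir, "manifest.tsv"),
           " already exists")
    }
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_genome_fasta(genome, file.path(outdir, "reference.fa"))
    write_genome_gtf(genome, file.path(outdir, "annotation.gtf"))
    for (smp in samples) {
      write_sam(smp$alignments, genome, file.path(outdir,
                                                  paste0(smp$sample_id, ".sam")))
    }
    write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth_table(out), file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    yaml::write_yaml(
      list(
        n_replicates_per_condition = config$n_replicates_per_condition,
        reads_per_sample = config$reads_per_sample,
        read_length = config$read_length,
        mito_fraction = as.list(config$mito_fraction),
        isoform_mixture = lapply(config$isoform_mixture, as.list),
        precursor_fraction = as.list(config$precursor_fraction),
        seed = config$seed
      ),
      file.path(outdir, "config.yaml")
    )
  }
  out
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("<sim_experiment> ", nrow(x$manifest), " samples (",
      paste(unique(x$manifest$condition), collapse = " vs "), "), ",
      x$config$reads_per_sample, " reads/sample\n", sep = "")
  invisible(x)
}

#' Long-format realized truth table of an experiment
#'
#' @param experiment A [simulate_experiment()] result.
#' @return Tibble with columns `sample_id`, `category`
#'   (`isoform`/`mito_unit`/`precursor`/`junction`/`border`), `key`, `reads`.
#' @export
truth_table <- function(experiment) {
  rows <- lapply(experiment$samples, function(smp) {
    tr <- smp$truth
    bind_rows(
      tibble::tibble(category = "isoform", key = tr$isoform_reads$isoform_id,
                     reads = as.numeric(tr$isoform_reads$reads)),
      tibble::tibble(category = "mito_unit", key = tr$unit_reads$transcript_id,
                     reads = as.numeric(tr$unit_reads$reads)),
      tibble::tibble(category = "precursor", key = "precursor",
                     reads = as.numeric(tr$precursor_reads)),
      tibble::tibble(
        category = "junction",
        key = sprintf("%s:%d-%d", tr$junction_reads$chrom,
                      tr$junction_reads$donor_end,
                      tr$junction_reads$acceptor_start),
        reads = as.numeric(tr$junction_reads$reads)
      ),
      tibble::tibble(
        category = "border",
        key = paste0(tr$border_reads$upstream_id, "|",
                     tr$border_reads$downstream_id),
        reads = as.numeric(tr$border_reads$reads)
      )
    ) %>% mutate(sample_id = smp$sample_id)
  })
  bind_rows(rows) %>% select(sample_id, category, key, reads)
}

#' Write alignments as a coordinate-sorted SAM file
#'
#' Single-end records with mapping quality 255, CIGAR built from the blocks
#' (`M` runs separated by `N` skips), no stored sequence.
#'
#' @param alignments Blocks tibble (`read_id`, `chrom`, `start`, `end`;
#'   0-based half-open) as produced by [simulate_sample()].
#' @param genome The [genome_model()] supplying `@SQ` header lines.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", genome$chromosomes$name,
            as.integer(genome$chromosomes$length))
  )
  if (nrow(alignments) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  recs <- alignments %>%
    arrange(read_id, start) %>%
    group_by(read_id, chrom) %>%
    summarise(
      pos = start[1] + 1,
      cigar = paste0(paste0(
        end - start, "M",
        ifelse(seq_along(start) < n(),
               paste0(pmax(dplyr::lead(start) - end, 0), "N"), "")
      ), collapse = ""),
      .groups = "drop"
    ) %>%
    arrange(match(chrom, genome$chromosomes$name), pos)
  lines <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                   recs$read_id, recs$chrom, as.integer(recs$pos), recs$cigar)
  writeLines(c(header, lines), path)
  invisible(path)
}
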