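#' Genome model
#'
#' A light container for a (toy or real) annotation: chromosomes with a
#' nuclear/mitochondrial compartment label and a circularity flag, plus
#' transcripts as ordered exon intervals.  All internal coordinates are
#' 0-based half-open; conversion to/from the 1-based inclusive GTF
#' convention happens only at the file boundary.
#'
#' @param chromosomes Tibble with columns `name`, `length`, `circular`
#'   (logical), `compartment` ("nuclear" or "mito").
#' @param transcripts Tibble with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype`.
#' @param exons Tibble with columns `transcript_id`, `exon_rank`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, transcripts, exons) {
  chromosomes <- tibble::as_tibble(chromosomes)
  transcripts <- tibble::as_tibble(transcripts)
  exons <- tibble::as_tibble(exons)
  stopifnot(
    all(c("name", "length", "circular", "compartment") %in% names(chromosomes)),
    all(c("transcript_id", "gene_id", "chrom", "strand", "biotype") %in%
          names(transcripts)),
    all(c("transcript_id", "exon_rank", "chrom", "start", "end") %in%
          names(exons))
  )
  if (!all(chromosomes$compartment %in% c("nuclear", "mito"))) {
    stop("chromosome compartment must be 'nuclear' or 'mito'")
  }
  if (!all(transcripts$chrom %in% chromosomes$name)) {
    stop("transcript on unknown chromosome: ",
         paste(setdiff(transcripts$chrom, chromosomes$name), collapse = ", "))
  }
  missing_ex <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(missing_ex)) {
    stop("transcript with zero exons: ", paste(missing_ex, collapse = ", "))
  }
  exons <- exons %>% arrange(transcript_id, start)
  exons <- exons %>%
    group_by(transcript_id) %>%
    mutate(exon_rank = seq_len(n())) %>%
    ungroup()
  # exon sanity per transcript: sorted, disjoint, inside the chromosome
  chr_len <- stats::setNames(chromosomes$length, chromosomes$name)
  if (any(exons$start < 0) || any(exons$end > chr_len[exons$chrom])) {
    stop("exon interval outside chromosome bounds")
  }
  if (any(exons$end <= exons$start)) stop("empty exon interval")
  by_tx <- split(exons, exons$transcript_id)
  for (tx in by_tx) {
    if (nrow(tx) > 1 && any(tx$start[-1] < tx$end[-nrow(tx)])) {
      stop("overlapping exons within transcript ", tx$transcript_id[1])
    }
  }
  structure(
    list(chromosomes = chromosomes, transcripts = transcripts, exons = exons),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$transcripts), " transcript(s), ",
      length(unique(x$transcripts$gene_id)), " gene(s)\n", sep = "")
  invisible(x)
}

#' Genomic span of each gene
#'
#' @param genome A [genome_model()].
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `compartment`
#'   (0-based half-open union span of all the gene's exons).
#' @export
gene_spans <- function(genome) {
  genome$exons %>%
    left_join(select(genome$transcripts, transcript_id, gene_id),
              by = "transcript_id") %>%
    group_by(gene_id, chrom) %>%
    summarise(start = min(start), end = max(end), .groups = "drop") %>%
    left_join(
      select(genome$chromosomes, chrom = name, compartment),
      by = "chrom"
    )
}

# single-exon transcript units on the mitochondrial chromosome, in genomic
# order; used by the simulator and the precursor-index module
mito_units <- function(genome) {
  mito_chrom <- genome$chromosomes$name[genome$chromosomes$compartment == "mito"]
  units <- genome$exons %>%
    filter(chrom %in% mito_chrom) %>%
    left_join(select(genome$transcripts, transcript_id, gene_id, biotype),
              by = "transcript_id") %>%
    arrange(start)
  multi <- units %>% count(transcript_id) %>% filter(n > 1)
  if (nrow(multi)) {
    stop("mitochondrial transcripts must be single-exon units: ",
         paste(multi$transcript_id, collapse = ", "))
  }
  units %>% select(transcript_id, gene_id, biotype, chrom, start, end)
}

#' Build the toy two-compartment genome
#'
#' One nuclear chromosome carries a 10-exon gene with two isoforms: a
#' full-length isoform using all nine junctions, and a 3'-only isoform that
#' starts at the anchor exon (exon 5) and uses only the downstream
#' junctions.  Shifting the isoform mixture therefore moves junction usage
#' reciprocally between the upstream and downstream junction groups.  One
#' circular mitochondrial chromosome carries seven abutting or
#' near-abutting single-exon transcript units (rRNA-like, mRNA-like and
#' short tRNA-like units interleaved), with the circular origin inside a
#' transcript-free spacer so no simulated alignment wraps it.
#'
#' @param config A [sim_config()]; isoform ids in its `isoform_mixture`
#'   must exist in the genome, and every isoform must be at least
#'   `read_length` long.
#' @return A [genome_model()] with attributes `anchor` (the coordinate that
#'   splits upstream from downstream junctions) and `seed`.
#' @examples
#' genome <- build_toy_genome(sim_config())
#' gene_spans(genome)
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))

  # nuclear gene: 10 exons of 150 nt, introns of 200 nt, starting at 500
  ex_starts <- 500 + (0:9) * 350
  nuc_exons <- tibble::tibble(
    transcript_id = "NUC1.full", exon_rank = 1:10, chrom = "chrN",
    start = ex_starts, end = ex_starts + 150
  )
  anchor_exon <- 5L
  short_exons <- nuc_exons %>%
    filter(exon_rank >= anchor_exon) %>%
    mutate(transcript_id = "NUC1.short", exon_rank = seq_len(n()))

  # mitochondrial transcript units (0-based half-open, genomic order);
  # MT.T2 sits 3 nt downstream of MT.P1 (near-abutting), all others abut
  mt <- tibble::tribble(
    ~transcript_id, ~biotype,         ~start, ~end,
    "MT.R1",        "Mt_rRNA",          300,  1250,
    "MT.T1",        "Mt_tRNA",         1250,  1320,
    "MT.P1",        "protein_coding",  1320,  2420,
    "MT.T2",        "Mt_tRNA",         2423,  2491,
    "MT.P2",        "protein_coding",  2491,  3291,
    "MT.T3",        "Mt_tRNA",         3291,  3363,
    "MT.P3",        "protein_coding",  3363,  3963
  )
  mt_exons <- mt %>%
    mutate(exon_rank = 1L, chrom = "chrM") %>%
    select(transcript_id, exon_rank, chrom, start, end)

  chromosomes <- tibble::tibble(
    name = c("chrN", "chrM"),
    length = c(4500L, 4300L),
    circular = c(FALSE, TRUE),
    compartment = c("nuclear", "mito")
  )
  transcripts <- bind_rows(
    tibble::tibble(
      transcript_id = c("NUC1.full", "NUC1.short"),
      gene_id = "NUC1", chrom = "chrN", strand = "+",
      biotype = "protein_coding"
    ),
    tibble::tibble(
      transcript_id = mt$transcript_id,
      gene_id = mt$transcript_id, chrom = "chrM", strand = "+",
      biotype = mt$biotype
    )
  )
  genome <- genome_model(chromosomes, transcripts,
                         bind_rows(nuc_exons, short_exons, mt_exons))

  # every nuclear isoform in the mixture must exist and fit a full read
  for (cond in config$conditions) {
    iso <- names(config$isoform_mixture[[cond]])
    unknown <- setdiff(iso, transcripts$transcript_id)
    if (length(unknown)) {
      stop("isoform_mixture names unknown transcripts: ",
           paste(unknown, collapse = ", "))
    }
    lens <- vapply(iso, function(id) {
      sum(with(genome$exons[genome$exons$transcript_id == id, ], end - start))
    }, numeric(1))
    if (any(lens < config$read_length)) {
      stop("isoform(s) shorter than read_length: ",
           paste(iso[lens < config$read_length], collapse = ", "))
    }
  }

  attr(genome, "anchor") <- list(
    gene_id = "NUC1",
    anchor_exon = anchor_exon,
    split_coord = ex_starts[anchor_exon]  # donor_end < this => upstream group
  )
  attr(genome, "seed") <- config$seed
  genome
}

#' Write reference sequences as FASTA
#'
#' Emits a random (but seed-deterministic) nucleotide sequence of the
#' declared length for every chromosome.  The sequences are placeholders:
#' the simulated alignments carry no sequence, so downstream statistics do
#' not depend on base content.
#'
#' @param genome A [genome_model()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seed <- attr(genome, "seed")
  if (is.null(seed)) seed <- 0L
  seqs <- withr_seed(seed, {
    vapply(seq_len(nrow(genome$chromosomes)), function(i) {
      paste(sample(c("A", "C", "G", "T"), genome$chromosomes$length[i],
                   replace = TRUE), collapse = "")
    }, character(1))
  })
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- genome$chromosomes$name
  Biostrings::writeXStringSet(xs, filepath = path)
  invisible(path)
}

# evaluate `expr` under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Write the annotation as GTF
#'
#' One `exon` feature per exon, with `gene_id`, `transcript_id` and
#' `gene_biotype` attributes; coordinates are converted from the internal
#' 0-based half-open representation to GTF's 1-based inclusive one.
#'
#' @param genome A [genome_model()].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_genome_gtf <- function(genome, path) {
  ex <- genome$exons %>%
    left_join(genome$transcripts, by = c("transcript_id", "chrom"))
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  gr$type <- "exon"
  gr$gene_id <- ex$gene_id
  gr$transcript_id <- ex$transcript_id
  gr$gene_biotype <- ex$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF annotation into a genome model
#'
#' Exon features are grouped by `transcript_id`; 1-based inclusive GTF
#' coordinates become 0-based half-open.  The compartment of each
#' chromosome is inferred from its name (`mito_chroms`); chromosome lengths
#' are taken from the file's sequence info when present, otherwise from the
#' right-most annotated coordinate.
#'
#' @param path GTF file.
#' @param mito_chroms Chromosome names treated as mitochondrial.
#' @return A [genome_model()].
#' @export
read_annotation <- function(path, mito_chroms = c("chrM", "MT", "chrMT")) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    stop("exon feature without transcript_id in ", path)
  }
  exons <- tibble::tibble(
    transcript_id = gr$transcript_id,
    exon_rank = NA_integer_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  biotype <- if (!is.null(gr$gene_biotype)) gr$gene_biotype else "protein_coding"
  transcripts <- tibble::tibble(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = exons$chrom,
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype
  ) %>% distinct(transcript_id, .keep_all = TRUE)
  sl <- GenomeInfoDb_lengths(gr)
  chrom_names <- unique(exons$chrom)
  lengths <- vapply(chrom_names, function(ch) {
    if (!is.na(sl[ch])) as.numeric(sl[ch]) else max(exons$end[exons$chrom == ch])
  }, numeric(1))
  chromosomes <- tibble::tibble(
    name = chrom_names,
    length = lengths,
    circular = chrom_names %in% mito_chroms,
    compartment = ifelse(chrom_names %in% mito_chroms, "mito", "nuclear")
  )
  genome_model(chromosomes, transcripts, exons)
}

GenomeInfoDb_lengths <- function(gr) {
  lens <- GenomeInfoDb::seqlengths(gr)
  if (is.null(lens)) {
    lens <- stats::setNames(rep(NA_real_, 0), character(0))
  }
  lens
}
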