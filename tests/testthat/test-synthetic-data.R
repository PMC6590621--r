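test_that("config validation enforces probabilities, mixtures and read length", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(mito_fraction = c(con = -0.1, ldl = 0.1)))
  expect_error(sim_config(read_length = 10))
  expect_error(sim_config(isoform_mixture = list(
    con = c(NUC1.full = 0.7, NUC1.short = 0.2),
    ldl = c(NUC1.full = 0.5, NUC1.short = 0.5)
  )), "sum to 1")
  expect_error(sim_config(precursor_fraction = c(con = 0.5)), "same condition")
})

test_that("toy genome satisfies the declared layout", {
  genome <- build_toy_genome(small_config())
  units <- mitosplice:::mito_units(genome)
  expect_gte(nrow(units), 6)
  # consecutive units abut or nearly abut (gap <= 5 nt)
  gaps <- units$start[-1] - units$end[-nrow(units)]
  expect_true(all(gaps >= 0 & gaps <= 5))
  # at least one short tRNA-like unit flanked by two long units
  lens <- units$end - units$start
  trna <- which(units$biotype == "Mt_tRNA")
  expect_true(any(trna > 1 & trna < nrow(units) &
                    lens[pmax(trna - 1, 1)] > 200 &
                    lens[pmin(trna + 1, nrow(units))] > 200))
  # chromosome flags
  expect_true(genome$chromosomes$circular[genome$chromosomes$name == "chrM"])
  expect_equal(genome$chromosomes$compartment, c("nuclear", "mito"))

  # nuclear junctions split into non-empty upstream/downstream sets
  anchor <- attr(genome, "anchor")
  full_map <- mitosplice:::spliced_map(genome, "NUC1.full")
  jx <- mitosplice:::transcript_junctions(full_map)
  expect_gte(nrow(full_map), 8)
  expect_true(any(jx$donor_end < anchor$split_coord))
  expect_true(any(jx$donor_end >= anchor$split_coord))
  short_map <- mitosplice:::spliced_map(genome, "NUC1.short")
  jx_short <- mitosplice:::transcript_junctions(short_map)
  expect_true(all(jx_short$donor_end >= anchor$split_coord))
})

test_that("genome build and sample simulation are deterministic", {
  cfg <- small_config(reads = 800)
  g1 <- build_toy_genome(cfg)
  g2 <- build_toy_genome(cfg)
  expect_identical(g1$exons, g2$exons)
  s1 <- simulate_sample(g1, cfg, "con", 2)
  s2 <- simulate_sample(g2, cfg, "con", 2)
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$truth, s2$truth)
  # different replicates differ
  s3 <- simulate_sample(g1, cfg, "con", 3)
  expect_false(identical(s1$alignments, s3$alignments))
})

test_that("per-sample truth counts are conserved and degenerate configs work", {
  cfg <- small_config(reads = 3000)
  genome <- build_toy_genome(cfg)
  smp <- simulate_sample(genome, cfg, "ldl", 1)
  tr <- smp$truth
  expect_equal(sum(tr$isoform_reads$reads) + sum(tr$unit_reads$reads) +
                 tr$precursor_reads, cfg$reads_per_sample)
  expect_equal(length(unique(smp$alignments$read_id)), cfg$reads_per_sample)

  # zero reads
  cfg0 <- small_config(reads = 0)
  s0 <- simulate_sample(build_toy_genome(cfg0), cfg0, "con", 1)
  expect_equal(nrow(s0$alignments), 0)
  expect_equal(sum(s0$truth$isoform_reads$reads), 0)

  # all reads mitochondrial
  cfgm <- sim_config(reads_per_sample = 2000,
                     mito_fraction = c(con = 1, ldl = 1), seed = 5)
  sm <- simulate_sample(build_toy_genome(cfgm), cfgm, "con", 1)
  expect_true(all(sm$alignments$chrom == "chrM"))
})

test_that("mature mito reads never span borders; precursor reads do so at the geometric rate", {
  cfg <- sim_config(reads_per_sample = 20000,
                    mito_fraction = c(con = 1, ldl = 1),
                    precursor_fraction = c(con = 0, ldl = 0.3), seed = 9)
  genome <- build_toy_genome(cfg)
  pairs <- enumerate_border_pairs(genome)

  mature <- simulate_sample(genome, cfg, "con", 1)
  bc0 <- count_border_spanning(mature$alignments, pairs, min_overlap = 1)
  expect_true(all(bc0$count == 0))

  pre <- simulate_sample(genome, cfg, "ldl", 1)
  n_pre <- pre$truth$precursor_reads
  units <- mitosplice:::mito_units(genome)
  span <- max(units$end) - min(units$start)
  rl <- cfg$read_length
  gap <- pairs$downstream_start - pairs$upstream_end
  expected <- n_pre * (rl - 2 * 6 + 1 - gap) / (span - rl + 1)
  observed <- count_border_spanning(pre$alignments, pairs, min_overlap = 6)$count
  expect_true(all(abs(observed - expected) <= 3 * sqrt(expected)))
})

test_that("realized junction counts follow the closed-form expectation", {
  cfg <- sim_config(reads_per_sample = 50000,
                    mito_fraction = c(con = 0, ldl = 0), seed = 31)
  genome <- build_toy_genome(cfg)
  smp <- simulate_sample(genome, cfg, "con", 1)
  rl <- cfg$read_length
  iso <- smp$truth$isoform_reads
  expected <- NULL
  for (i in seq_len(nrow(iso))) {
    map <- mitosplice:::spliced_map(genome, iso$isoform_id[i])
    jx <- mitosplice:::transcript_junctions(map)
    L <- sum(map$exon_length)
    p <- (rl - 1) / (L - rl + 1)
    jx$mu <- iso$reads[i] * p
    jx$v <- iso$reads[i] * p * (1 - p)
    expected <- rbind(expected, jx[, c("donor_end", "acceptor_start", "mu", "v")])
  }
  expected <- aggregate(cbind(mu, v) ~ donor_end + acceptor_start,
                        data = expected, FUN = sum)
  obs <- merge(as.data.frame(smp$truth$junction_reads), expected,
               by = c("donor_end", "acceptor_start"))
  expect_equal(nrow(obs), 9)
  # family-wise: aggregate deviation within 3 SD, each of the nine
  # junctions within 4 SD (a per-junction 3-SD bound over nine draws
  # would fail by chance alone in a few percent of seeds)
  z_total <- sum(obs$reads - obs$mu) / sqrt(sum(obs$v))
  expect_lt(abs(z_total), 3)
  expect_true(all(abs(obs$reads - obs$mu) <= 4 * sqrt(obs$v)))
})

test_that("experiment driver writes a complete, reproducible bundle", {
  cfg <- small_config(reads = 300)
  outdir <- withr::local_tempdir()
  exp <- simulate_experiment(cfg, outdir = outdir)
  expect_equal(nrow(exp$manifest), 8)
  expect_setequal(
    list.files(outdir),
    c("annotation.gtf", "config.yaml", "manifest.tsv", "reference.fa",
      "truth.tsv", paste0(exp$manifest$sample_id, ".sam"))
  )
  # collision guard
  expect_error(simulate_experiment(cfg, outdir = outdir), "collision")

  # same seed twice: identical truth tables
  exp2 <- simulate_experiment(cfg)
  expect_identical(truth_table(exp), truth_table(exp2))
})

test_that("realized mito fraction concentrates on its design value", {
  cfg <- sim_config(reads_per_sample = 100000, n_replicates_per_condition = 1,
                    seed = 77)
  genome <- build_toy_genome(cfg)
  for (cond in c("con", "ldl")) {
    smp <- simulate_sample(genome, cfg, cond, 1)
    frac <- length(unique(smp$alignments$read_id[smp$alignments$chrom == "chrM"])) /
      cfg$reads_per_sample
    expect_lt(abs(frac - cfg$mito_fraction[[cond]]), 0.01)
  }
})
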