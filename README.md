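# mitosplice

Statistics for two phenomena that ordinary gene-level RNA-seq analysis
glosses over: *which splice sites a gene actually uses*, and *what the
mitochondrial transcriptome is doing*.

The package grew out of a study design in which endothelial cells under a
lipid stress shifted NOS3 splice-site usage toward non-functional isoforms
while globally upregulating mitochondrial transcripts. It provides, as
reusable and tested R functions:

- **GNSSR** — gene-normalized splice-site usage. For junction `j` in sample
  `s`,

  ```
  GNSSR(j, s) = [ c(j,s) / G(s) ] / [ g(gene,s) / T(s) ]
  ```

  where `c(j,s)` is the junction read count, `G(s)` the sample's total
  gapped (junction) reads, `g(gene,s)` the union-mode read count of the
  junction's host gene and `T(s)` the total mapped reads. Junction groups
  (e.g. upstream vs downstream of an anchor exon) are averaged per sample
  and compared between conditions with an unpaired Student's t-test.
- **Nuclear/mitochondrial read partition** — per-sample percentages of
  reads on each compartment, plus a simple CPM + t-test + Benjamini-
  Hochberg summary of per-gene mitochondrial expression changes.
- **Precursor index** — the abundance of unprocessed polycistronic
  mitochondrial precursor RNA, estimated from ungapped reads that span the
  border between neighboring mitochondrial transcript units by at least 6
  nt on each side, normalized to the sample's ungapped reads and its
  mitochondrial ungapped fraction, and averaged over borders.
- **qPCR quantification** — `2^-ΔCt` relative expression against a
  reference transcript (RPL32-style) and relative mtDNA copy number
  against a single-copy nuclear locus (NXN-style), with group summaries.
- **A deterministic simulator** — a toy two-compartment genome (one
  10-exon nuclear gene with full-length and 3'-truncated isoforms; one
  circular mitochondrial chromosome with seven abutting transcript units)
  and single-end aligned reads with controllable isoform mixture,
  mitochondrial read fraction and precursor fraction, written as standard
  FASTA/GTF/SAM so every statistic can be checked against ground truth.

## Worked example

```r
library(mitosplice)

cfg <- sim_config(reads_per_sample = 20000, seed = 3)
exp <- simulate_experiment(cfg)

res <- gnssr_analysis(exp)
res$comparison[, c("group", "mean_a", "mean_b", "t", "p")]
#> # A tibble: 2 × 5
#>   group      mean_a mean_b     t            p
#>   <chr>       <dbl>  <dbl> <dbl>        <dbl>
#> 1 downstream 0.135  0.175  -41.4 0.0000000133
#> 2 upstream   0.0933 0.0642  30.1 0.0000000894
```

The default configuration shifts the full-length/truncated isoform mixture
from 0.8/0.2 ("con") to 0.5/0.5 ("ldl"): junctions upstream of the anchor
exon (used only by the full-length isoform) lose usage while downstream
junctions gain it — the reciprocal pattern the statistic is designed to
detect, here at p < 1e-7 with 4 replicates per condition.

```r
mp <- mito_profile(exp)
head(mp$profile, 2)
#>   sample_id nuclear_pct mito_pct total_reads
#> 1 con_1            95.3     4.68       20000
#> 2 con_2            95.7     4.34       20000

pa <- precursor_analysis(exp)
pa$comparison$p   # equal precursor fractions by design -> not significant
#> [1] 0.110
```

Writing `simulate_experiment(cfg, outdir = "sim")` produces
`reference.fa`, `annotation.gtf`, one coordinate-sorted SAM per sample, a
manifest, the realized truth table and a YAML echo of the configuration;
`read_annotation()` and `read_alignments()` load such files (or any
GTF/SAM/BAM with single-end reads) back into the analysis path.

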