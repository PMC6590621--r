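---
title: "Splice-site usage and mitochondrial transcriptome statistics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-site usage and mitochondrial transcriptome statistics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosplice)
```

This vignette explains the statistics the package implements, the
assumptions behind them, the design choices that were genuinely open, and
what the simulation-based validation does and does not establish.

## 1. The biological setting

Two transcriptomic phenomena motivate the package. First, a gene's overall
read count can hide isoform shifts: when a stressor pushes transcription
toward a 3'-truncated isoform, total expression may barely move while the
protein-coding output collapses. Exon–exon junction reads — alignments
whose CIGAR contains skip (`N`) operations — carry the isoform signal
directly, because each junction belongs to a specific subset of isoforms.
Second, the mitochondrial genome is transcribed as long polycistronic
precursors that are cleaved by RNase P and RNase Z at the boundaries of
the encoded tRNAs ("tRNA punctuation"). A read that straddles the border
between two neighboring mature transcripts can only derive from the
unprocessed precursor, so border-spanning coverage is a direct, if sparse,
readout of precursor abundance.

## 2. Gene-normalized splice-site usage (GNSSR)

For junction $j$ in sample $s$:

$$\mathrm{GNSSR}(j,s) = \frac{c(j,s)\,/\,G(s)}{g(\mathrm{gene},s)\,/\,T(s)}$$

with $c$ the junction read count, $G$ the sample's total gapped reads, $g$
the union-mode read count of the junction's host gene and $T$ the total
mapped reads. The first ratio normalizes a junction against overall
splicing-informative sequencing depth; the second corrects for the host
gene's expression level, so that a change in GNSSR reflects *relative*
splice-site use, not differential gene expression. The statistic is
invariant under uniform scaling of all counts, hence comparable across
libraries of different depth.

Two functional-form choices were open and are resolved as follows:

- **Normalizer form.** The two normalizers are combined as a ratio of
  ratios. Absolute GNSSR magnitudes therefore carry no unit and are not
  comparable across different definitions of the gene normalizer; an
  optional `scale` factor (default 1) affects readability only. Only
  ratios between samples, signs of changes and test decisions are
  interpreted.
- **Gene normalizer.** Union-mode gene counts over total mapped reads.
  TPM-style length normalization would cancel in any between-sample
  comparison of the same junction and is not implemented.

Junctions are attributed to the single gene whose genomic span contains
both the donor and the acceptor coordinate; junctions matching zero or
several genes are flagged and excluded from aggregation, as are junctions
of genes with zero counts (the ratio is undefined there).

**Group aggregation.** A junction group (e.g. "all junctions upstream of
the anchor exon") is summarized per sample as the arithmetic mean of GNSSR
over the group's junction *universe* — the junctions observed in at least
one sample of the experiment. A junction observed in some samples
contributes 0 where it is unobserved (absence of evidence for use *is*
evidence of low usage at comparable depth); junctions observed nowhere are
excluded, because they would only dilute every sample equally. Groups are
compared between conditions with an unpaired two-sided Student's t-test on
the per-sample means.

## 3. Read model and counting rules

Internal coordinates are 0-based half-open throughout; GTF input/output is
converted at the file boundary (1-based inclusive). Alignment blocks are
derived from CIGAR strings with the standard semantics: `M/=/X` advance
both sequences, `N` splits blocks (a junction), `D` advances the reference
*within* a block (a deletion is not splicing evidence), `I/S` advance the
query only. A read is *gapped* iff it has at least two blocks; each
adjacent block pair defines one junction key (donor end, acceptor start).
Unmapped, secondary and supplementary records are skipped; duplicates are
not removed.

Gene-level counting is union-mode with ambiguity discarding: a read is
assigned to a gene only if every one of its blocks overlaps that gene's
exons and no block overlaps any other gene. Reads touching no gene
(`no_feature`) or several genes (`ambiguous`) are tallied but excluded, so
that assigned + ambiguous + no_feature equals the mapped-read total — an
invariant the tests enforce.

## 4. The precursor border-coverage index

Mitochondrial transcript units are sorted by genomic start; each adjacent
couple defines a border pair. An *ungapped* read $[a,b)$ is counted for a
pair with upstream end $e$ and downstream start $d$ iff

$$e - a \ge m \quad\text{and}\quad b - d \ge m,$$

with minimal overlap $m = 6$ nt by default. Gapped reads are excluded:
the normalization is defined in terms of ungapped reads, and a spliced
read is mature by definition. For near-abutting neighbors (gap of a few
nt) each condition applies to its own coordinate, so a read lying wholly
inside the gap counts for neither side. A read long enough to span a very
short intervening tRNA entirely may satisfy two pairs and is counted for
each; with desk-scale read lengths this is rare and flagged nowhere else.

Raw counts are normalized per sample to the total ungapped reads $U$ and
the mitochondrial ungapped fraction $m_u$:
$\mathrm{norm} = 10^6 \cdot b / (U \cdot m_u)$, and averaged over border
pairs into the per-sample *precursor index*. The $10^6$ scale is cosmetic.
Normalizing by the mitochondrial fraction makes the index a *processing*
readout: a sample with twice the mitochondrial output but identical
processing efficiency gets the same index.

The pair across the circular origin is excluded by default — linear
aligners do not produce origin-wrapping alignments — and can be included
with `include_origin = TRUE` where such alignments exist.

## 5. qPCR quantification

Relative expression is $2^{-\Delta C_t}$ with
$\Delta C_t = C_t(\text{target}) - C_t(\text{reference})$, assuming
perfect doubling per cycle; no amplification-efficiency correction is
applied. Technical replicates are averaged on the $C_t$ scale, which is a
geometric mean on the quantity scale — the standard convention for
exponential-phase measurements. mtDNA copy number uses the identical form
against a single-copy nuclear locus. Optional no-RT ("mock") controls flag
a measurement as possibly DNA-contaminated when the mock $C_t$ comes
within 5 cycles of the RT $C_t$; flagged values are reported, not
silently dropped, leaving the judgement to the analyst.

## 6. Statistical primitives

"Student's t-test" is implemented as the classical pooled-variance form
(Welch available behind a flag), two-sided throughout. Degenerate inputs
are resolved deterministically: zero variance in both groups with equal
means gives $t=0, p=1$; with unequal means the comparison is certain at
the observed resolution and is reported as $p=0$ with a `degenerate`
flag rather than as an error. Multiple testing across gene sets uses the
Benjamini–Hochberg step-up adjustment.

## 7. What the simulator emulates — and what it does not

The generator's defaults mirror the study design the package models: two
conditions ("con", "ldl") × 4 replicates of single-end reads; a
mitochondrial read fraction of 4.5% vs 11.2%; a nuclear isoform mixture
of 0.8/0.2 (full-length/3'-truncated) shifting to 0.5/0.5; an unchanged
precursor fraction of 5% in both conditions; read length 100 nt. The
default 100,000 reads per sample is a desk-scale choice; individual
analyses in the tests use 4,000–100,000 reads per sample, chosen so that
every targeted effect is detectable while a full validation run completes
on a laptop.

The toy genome has one nuclear chromosome (a 10-exon gene, 150-nt exons,
200-nt introns; the truncated isoform starts at exon 5, the anchor) and
one circular mitochondrial chromosome with seven single-exon units —
rRNA-like, mRNA-like and three short tRNA-like units — abutting or
separated by ≤3 nt, with the origin inside a transcript-free spacer.

Reads are placed uniformly: on the spliced transcript for nuclear reads
(blocks obtained by projecting through the exon map), uniformly on the
contiguous transcript-unit span for precursor reads, and uniformly within
a length-weighted mature unit otherwise. Mature reads on units shorter
than the read length are truncated to the unit, which keeps the defining
property *mature reads never cross a border* exact. All randomness derives
deterministically from (seed, condition, replicate).

Deliberately **not** modelled: sequencing errors and quality values,
fragment-length and GC bias, strand-specific counting (all toy transcripts
are plus-strand; the statistics under test are strand-agnostic),
paired-end reads, multimappers, rRNA contamination, reads wrapping the
circular origin, and the light-strand antisense transcripts of a real
mitochondrial genome. Consequently, passing the simulation-based tests
shows that the *estimators are correct for their definitions* and behave
as designed under known mixtures — it does not show robustness to
alignment artifacts or library-preparation biases in real data, where the
usual QC upstream of this package remains necessary.

## 8. Numerical and degenerate-input choices

- Junction truth in the simulator is computed from spliced coordinates
  independently of the block projection, so the SAM round-trip tests
  compare two genuinely different code paths.
- `reads_per_sample = 0`, all-mito and all-precursor configurations are
  valid and tested; isoforms shorter than the read length are rejected at
  genome construction.
- A sample with no mitochondrial ungapped reads but nonzero border counts
  is an inconsistency and raises an error; with zero counts it yields
  index 0.
- BH adjustment is order-preserving and clipped at 1; adjusted values are
  monotone in rank, which the tests assert on random inputs.
- Expected border counts follow a closed form used as an oracle: for a
  pair with gap $\gamma$, a precursor read of length $L$ has
  $L - 2m + 1 - \gamma$ eligible start positions, out of
  $S - L + 1$ on a unit span of length $S$.

## 9. Known limitations

- GNSSR magnitudes are not comparable across different gene-normalizer
  conventions; only within-analysis contrasts are meaningful.
- The t-test-on-log-CPM differential-expression summary is a surrogate
  for count-based models (negative-binomial GLMs); it is labelled as such
  in its output and should not be used for genome-scale inference on real
  data.
- The precursor index is a relative, not absolute, measure of processing:
  it cannot distinguish faster cleavage from faster precursor degradation.
- Union-mode counting discards ambiguous reads entirely; on compact
  genomes with overlapping genes (as in real mitochondria, where heavy-
  and light-strand transcripts overlap) a strand-aware counter would be
  required.
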