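---
title: "Quantifying aberrant antisense transcription with antisenseq"
author: "antisenseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying aberrant antisense transcription with antisenseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antisenseq)
```

## The biological problem

Transcription elongation leaves chromatin transiently exposed, and cells
rely on co-transcriptional chromatin marks to prevent spurious
transcription initiation inside gene bodies — much of it on the strand
opposite the annotated gene ("antisense" transcription). In fission
yeast, the elongation kinase Cdk9 (which phosphorylates Spt5) and
mono-ubiquitylation of histone H2B (H2Bub1) both feed into the Clr6-CII
/ Rpd3S histone-deacetylase pathway that keeps gene bodies transcriptionally
silent on the antisense strand. Acutely inhibiting an analog-sensitive
Cdk9, removing H2Bub1 with a histone point mutation, or doing both,
de-represses antisense transcripts at overlapping but distinct gene
sets, with a strongly synergistic double-perturbation effect.

`antisenseq` re-implements the computational side of that style of
study as a reusable, tested pipeline:

1. **Strand-specific classification.** Each aligned read interval is
   classified against a gene annotation as *sense* (maps to an annotated
   gene on its own strand), *antisense* (maps opposite a single
   annotated protein-coding gene; reads antisense to more than one gene
   are *discarded* as unassignable), or *intergenic* (between annotated
   loci, tallied in fixed 500-bp windows).
2. **RPKM quantification** per feature and strand class, averaged over
   replicate libraries.
3. **Differential calling** against wild type with the field's simple
   rule: at least 2-fold change in log2 space (strictly `> 1` or
   `< -1`) *and* the larger of the two RPKM values above 1 — a noise
   floor, not a statistical test.
4. **Set statistics**: hypergeometric overlap of antisense-up sets
   between perturbations, Mann–Whitney synergy on per-gene fold
   inductions, and one-sided Fisher term enrichment with Bonferroni
   correction.
5. **Spike-in ChIP signal analysis**: IP/input ratio tracks scaled by
   spike-in recovery, antibody ratio tracks (e.g. pSpt5:Spt5), anchored
   (TSS/CPS ± flank) and gene-scaled metagene matrices, occupancy-based
   gene clustering, and a trough statistic for the characteristic dip in
   polymerase occupancy over the cleavage-and-polyadenylation site
   (CPS).
6. **A synthetic-data generator** with planted ground truth, so the
   whole chain is testable end-to-end without any external data.

## Containers and conventions

The package is organised around S4 classes: `GenomeAnnotation` (a
`GRanges` of gene features plus chromosome sizes), `StrandedCounts`,
`ExpressionTable`, `CoverageTrack`, `MetageneMatrix` and
`SyntheticDataset`. All internal coordinates follow the Bioconductor
convention — 1-based, closed intervals — with BED's 0-based half-open
coordinates converted at the file boundary by `rtracklayer`. Using one
internal convention everywhere avoids off-by-one drift between modules;
GFF3 needs no conversion. TSS and CPS anchors are derived from the
annotated feature endpoints (5' and 3' ends on the gene's strand); no
UTR model is applied because gene-level annotations carry none.

Interval queries are delegated to `GenomicRanges::findOverlaps`, and the
classifier, the overlap query and the metagene windowing are all
property-tested against naive brute-force enumerations.

### Classification rule details

The published definitions leave three situations open; the package fixes
them deterministically and exposes each as a parameter:

- a read overlapping several same-strand genes is assigned to the gene
  with the **largest overlap**, ties broken by lexicographically
  smallest gene id;
- a read overlapping genes on **both** strands is sense — this prevents
  ordinary sense reads of overlapping gene pairs from inflating
  antisense counts;
- the minimum overlap to count is 1 bp (`minOverlap`).

Antisense calls are restricted to protein-coding host genes by default
(`antisenseBiotypes`), since the sense universe is the protein-coding
gene set; reads antisense to non-coding loci fall outside both the
gene-hosted classes and the intergenic windows and are tallied
separately (`intergenicUnbinned`) so that read conservation —
sense + antisense + intergenic + discarded = input — holds exactly for
every library.

The RPKM library size is, by default, the sample's **assigned** read
total (sense + antisense + intergenic); discarded reads are ambiguous
signal rather than expression. The alternative definition including
discarded reads is available via `librarySize = "all"`.

### Differential-call semantics

`callDifferential()` computes `log2((mut + psi)/(wt + psi))` with a
pseudocount `psi = 0.1` RPKM whose only job is to keep the ratio finite
at zero; the 1-RPKM floor is the actual noise control. Both
inequalities are **strict**: a feature at exactly 2.0-fold (with
`psi = 0`), or with a maximum of exactly 1 RPKM, is `unchanged`. The
"maximum" is taken over the two compared conditions. No multiple-testing
correction is applied to per-gene calls — the rule is a threshold, not a
test — and corrections appear only where a test is actually performed
(Bonferroni over enrichment terms).

### Statistics

The hypergeometric overlap p-value is the upper tail
`P[X >= |A ∩ B|]` with population `|universe|`, the universe being the
protein-coding genes eligible for antisense calling. The Mann–Whitney
test is implemented in the package (rather than calling
`stats::wilcox.test`) so that the exact small-sample path handles ties:
for both sample sizes at most 8 it enumerates all labelings of the
pooled values and reports the two-sided tail of the permutation
distribution; above that it uses the normal approximation with tie
correction and continuity correction. `wilcox.test` serves as an
independent cross-check in the test suite, never as the implementation.
Fisher term enrichment is one-sided (`greater`), which the suite checks
against the hypergeometric tail identity on all small tables.

## The synthetic-data generator

The generator is first-class, tested code. It emulates the study design
the pipeline targets: four strains — wild type, an analog-sensitive
kinase mutant (effect only under inhibitor), a constitutive histone
mutant, and the double mutant — crossed with two treatments (vehicle
and inhibitor), with duplicate libraries of 1M single-end 50-nt reads
each over ~2000 genes on a two-chromosome toy genome.

Antisense induction is planted in four disjoint protein-coding subsets
(defaults 60/60/30/400): kinase-only and histone-only genes respond to
their own perturbation at 4-fold; `shared` genes respond to either;
`double_only` genes respond only in the drug-treated double mutant. In
that double condition, single-perturbation genes are induced at
`synergyFactor = 3` times the single fold (12-fold), reproducing the
~4-fold vs ~12-fold median-induction contrast that motivates the
synergy analysis.

Numerical choices worth knowing:

- **Closure.** Configured expression levels are *relative weights*:
  expected counts are normalized so every library's expected total
  equals `depth`. The truth table records the implied expected RPKM on
  the realized scale, so RPKM-space thresholds (the 1-RPKM floor, the
  "baseline ≥ 5 RPKM" detectability condition) are well defined.
- **Baselines.** Sense levels are log-normal (median 250 RPKM —
  appropriate for a megabase-scale genome sequenced to 1M reads);
  unplanted antisense background is 0.05 RPKM, one to two orders below
  planted baselines (uniform 8–20 RPKM), reflecting how low antisense
  leakage is in poly(A) libraries relative to sense signal. Intergenic
  background takes 2% of each library.
- **Noise.** Poisson by default; negative binomial (`nbSize`) for
  overdispersion studies; `"none"` rounds expectations and spaces reads
  evenly, for exact-recovery tests.
- **Reads** are single-end fixed-length intervals whose strand *is* the
  transcript strand; the classifier's convention flag, not the
  generator, models dUTP-style libraries. Sequencing error, mappability
  and PCR duplicates are out of scope.

The ChIP generator builds per-base IP tracks as a flat background plus a
per-gene shape: a 5' ramp, a plateau proportional to a log-normal
expression score, an optional Gaussian TSS-proximal peak, a flat-cored
cosine-tapered trough of configurable depth centred on the CPS, and a
300-bp post-CPS shoulder decaying to background. The flat trough core
makes the binned profile minimum equal `1 - troughDepth` in closed
form, and the intergenic gaps of the toy genome (800–1500 bp) are sized
so a gene's CPS-window shoulders are not contaminated by its
neighbour's 3' tail. Input tracks are flat, and spike-in chromatin is
represented as scalar read counts per library — a fixed fraction of
the track total — because the normalization formula consumes nothing
else.

Setting `troughDepth = 0` in a condition reproduces the effaced-trough
regime observed in H2Bub1-deficient cells; the default `chipConfig()`
pairs that condition with a 0.6-deep control so the contrast is
available out of the box.

## Spike-in normalization

ChIP signals are computed per bin as
`scale * (IP + psi) / (input + psi)` with
`scale = input_spike_reads / ip_spike_reads`. This input-anchored form
cancels both IP efficiency and sequencing depth: multiplying one
sample's target and spike reads by any constant leaves its normalized
track unchanged (up to the pseudocount), and equal spike recovery
reduces the signal to plain IP/input. For cross-sample comparisons of
IP signals against a common reference, `spikeScaleToReference()`
provides the alternative `ref_spike / sample_spike` factor. The ratio
pseudocount defaults to 1 raw-coverage unit, and bins with input below
a configurable floor can be masked to avoid spurious extreme ratios.

## Metagene analysis

`anchoredMatrix()` averages signal in fixed-width bins over
`[anchor - upstream, anchor + downstream)` in each gene's 5'→3'
orientation; minus-strand rows are flipped at construction so bin 1 is
always 5'-most, making strand mirroring an exact invariance.
`scaledMatrix()` resamples the gene body — by default trimmed 200 bp
inside each end, in 100 bins — so bodies of different length align.
Genes whose window leaves the chromosome, or whose trimmed body is
shorter than the bin count, are dropped with a message rather than
padded, avoiding edge bias. Genes overlapping another gene within the
window are retained (no published filter exists to mimic); callers can
pass an explicit `geneIds` subset instead of guessing.

`troughStatistic()` reports `min(window) / mean(edge bins)` around an
anchor — 1.0 for a flat profile, approximately `1 - depth` for a
planted trough. The flank must be wide enough that the window edges sit
on the shoulders; with 50-bp bins the default 5-bin flank (250 bp)
clears the 150-bp trough half-width. `clusterGenes()` orders genes by
an occupancy score, high to low, and slices fixed-size blocks (500
genes by default) or equal-count quantile groups, with gene-id
tie-breaks for determinism.

## The pipeline

`runPipeline(pipelineConfig(), outDir, seed)` chains the stages:
simulate → quantify → call (each mutant × treatment against wild type
under the same treatment) → compare (overlap/synergy/enrichment over
the drug-treated antisense-up sets) → ChIP/metagene → truth evaluation
(confusion matrix, sensitivity, FDR per comparison) → report. All
intermediates are plain text, every reported number is recomputable
from them, and outputs are byte-identical for a fixed configuration and
seed (wall-clock timings go only to `pipeline.log`). A thin
command-line wrapper lives at `inst/scripts/run-antisenseq.R`;
`validateRunConfig()` returns diagnostics (missing replicates,
out-of-range thresholds, inconsistent metagene geometry) without
raising.

```{r demo, eval = FALSE}
cfg <- pipelineConfig(
  rnaseq = rnaSeqConfig(nGenes = 300L, depth = 1e5,
                        subsetSizes = c(cdk9_only = 12L, h2bub1_only = 12L,
                                        shared = 8L, double_only = 40L)),
  clusterSize = 100L)
report <- runPipeline(cfg, "demo_run", seed = 1)
report$overlap$shared_cdk9as_htb1K119R
report$chip$control$trough_statistic
```

## What the tests show — and what they do not

The test suite validates the machinery, not the biology: classification
and windowing against brute-force oracles on randomized annotations
with engineered overlaps; exact read conservation; RPKM and averaging
against one-line formulas; the statistics against enumeration and
closed-form identities; planted-truth recovery (exact at zero noise;
sensitivity ≥ 0.95 at Poisson noise and study depth for 4-fold effects
above 5 RPKM baseline); spike-in depth invariance; and trough-depth
recovery in both regimes. Problem sizes in the suite — 2000 genes, 1M
reads, five replicate seeds for the noise study; 10,000 reads × 300
genes × 10 seeds for the classifier property — were chosen as the
smallest sizes at which the planted structure is comfortably resolved.

Because the generator's reads are uniform within features, real-data
phenomena — 3' bias, mappability gaps, PCR duplicates, overdispersion
beyond the negative binomial, convergent read-through transcription —
are *not* represented, so passing tests certify correctness of the
computations under the stated model, not performance on any particular
sequencing run. Likewise the synthetic term map plants its own
enrichment structure; it says nothing about real functional annotation.

## Known limitations

- Counting is read-level, not fragment-level; paired-end data should be
  reduced to fragments (or one mate) upstream.
- The RPKM library-size definition is a genuine degree of freedom in
  published work; both options are implemented, and results quoted from
  this package should state which was used.
- Isoforms, UTRs and transcript assembly are out of scope; antisense is
  defined purely against gene-level intervals.
- The trough statistic assumes its window edges sit on plateau signal;
  profiles from annotations with very short genes or very short
  intergenic gaps violate that geometry and need wider flanks or
  per-gene inspection.
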