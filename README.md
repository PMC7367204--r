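# antisenseq

Strand-specific antisense transcription analysis with spike-in
normalized ChIP profiling, built on the Bioconductor stack
(GenomicRanges, rtracklayer, S4 classes).

## The problem

Elongating RNA polymerase II transiently disrupts chromatin, and cells
use co-transcriptional marks — Cdk9-dependent Spt5 phosphorylation and
histone H2B mono-ubiquitylation (H2Bub1), feeding into the Clr6-CII /
Rpd3S histone deacetylase — to suppress aberrant transcription
initiation inside gene bodies, much of it antisense to the host gene.
Studies of this pathway in fission yeast compare strand-specific
RNA-seq across a 4-strain × 2-treatment design (wild type, an
analog-sensitive kinase mutant, a histone point mutant, the double
mutant; vehicle vs inhibitor) and relate antisense de-repression to
chromatin state measured by spike-in normalized ChIP-seq.

`antisenseq` packages that desk-side analysis for anyone doing similar
work:

- **Classification**: each stranded read interval is *sense* (maps to
  an annotated gene on its own strand), *antisense* (maps opposite
  exactly one protein-coding gene; reads antisense to more than one
  gene are *discarded*), or *intergenic* (tallied in 500-bp windows
  between loci). Conservation — sense + antisense + intergenic +
  discarded = input reads — holds exactly.
- **Quantification**: RPKM per feature and strand class
  (`count × 10^9 / (length × library)`), averaged over replicates.
- **Differential calls** vs wild type: strictly more than 2-fold in
  log2 space, with `max(mut, wt) > 1` RPKM as a noise floor.
- **Statistics**: hypergeometric overlap of antisense-up gene sets,
  Mann–Whitney synergy on per-gene fold inductions (exact, tie-aware
  permutation for small samples), Fisher/Bonferroni term enrichment.
- **ChIP**: spike-in scaled IP/input signal
  (`scale = input_spike / ip_spike`), antibody ratio tracks, TSS/CPS
  anchored and gene-scaled metagene matrices, occupancy-ordered gene
  clustering, and a CPS trough-depth statistic.
- **Synthetic data**: a deterministic generator plants antisense
  induction in configurable gene subsets (kinase-only, histone-only,
  shared, double-only; 4-fold single, 12-fold double by default) and
  emits reads, ChIP tracks with spike-in counts, and a ground-truth
  table — so the entire pipeline is testable with no downloads.

## Worked example

A small end-to-end run — 300 genes, 16 libraries of 100k reads,
noise-free generation so planted truth is recovered exactly:

```r
library(antisenseq)

cfg <- pipelineConfig(
  rnaseq = rnaSeqConfig(nGenes = 300L, depth = 1e5, noise = "none",
                        subsetSizes = c(cdk9_only = 12L, h2bub1_only = 12L,
                                        shared = 8L, double_only = 40L)),
  clusterSize = 100L)
report <- runPipeline(cfg, "demo_run", seed = 1)
```

`demo_run/report.md` then reads (verbatim):

```
## Antisense up-calls (drug-treated, vs wild type)

- cdk9as: 20 genes (7.0% of protein-coding)
- htb1K119R: 20 genes (7.0% of protein-coding)
- cdk9as_htb1K119R: 72 genes (25.3% of protein-coding)

- shared (kinase & histone single mutants): 8 genes
- overlap cdk9as vs htb1K119R: 8 genes, hypergeometric log10(p) = -4.997

## Synergy over the shared antisense set

- median fold induction: double 11.48 vs single  4.04 /  4.04
- Mann-Whitney p (double vs kinase single): 0.0001554

## ChIP trough statistics

- control: trough = 0.4252 (spike scale 0.4051)
- h2bub1_deficient: trough =     1 (spike scale 0.3804)

## Truth recovery

- cdk9as_3MBPP1: sensitivity     1, FDR     0 (TP 20, FP 0, FN 0)
```

Reading this: each single perturbation de-represses antisense at its
own planted genes (12 private + 8 shared = 20; 7% of the coding
universe), the drug-treated double mutant hits all planted subsets (72
genes, 25%), the single-mutant sets overlap far beyond chance (p ≈
10⁻⁵), shared genes are induced ~4-fold by either single perturbation
but ~11.5-fold in the double mutant (the planted 3× synergy), the
ChIP trough statistic reads the planted 0.6-deep CPS trough as ≈0.4
and the effaced regime as 1.0, and the differential caller recovers the
planted truth exactly at zero noise. `demo_run/` also holds every
intermediate (counts, RPKM, calls, profiles, clusters) as TSV/JSON.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/run-antisenseq.R --out demo_run --seed 1
```

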