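## Synthetic data with planted ground truth.
##
## The RNA-seq generator emulates a 4-strain x 2-treatment fission-yeast
## style design: wild type, an analog-sensitive kinase mutant whose
## effect requires the inhibitor, a constitutive histone-mutant, and the
## double mutant, with antisense induction planted in four disjoint gene
## subsets (kinase-only, histone-only, shared, double-only). Configured
## expression levels are relative weights; expected counts are normalized
## so each library's expected total equals `depth`, and the truth table
## records the implied expected RPKM on the realized scale.

.STRAINS <- c("WT", "cdk9as", "htb1K119R", "cdk9as_htb1K119R")
.TREATMENTS <- c("DMSO", "3MBPP1")

#' RNA-seq generator configuration
#'
#' Defaults define the study conditions: ~2000 genes on a 2-chromosome
#' toy genome, duplicate 1M-read libraries per strain x treatment,
#' Poisson count noise, antisense background far below sense (0.05 RPKM),
#' planted antisense baselines of 8-20 RPKM induced 4-fold by a single
#' perturbation and 12-fold (synergy factor 3) in the drug-treated double
#' mutant.
#'
#' @param nGenes Number of genes.
#' @param nChroms Number of chromosomes.
#' @param geneLengthRange,gapRange Uniform ranges (bp) for gene lengths
#'   and intergenic gaps.
#' @param nonCodingFraction Fraction of genes labelled `non_coding`.
#' @param readLength Read length in bp (single-end intervals).
#' @param depth Expected reads per library.
#' @param replicates Libraries per strain x treatment.
#' @param noise `"poisson"`, `"nbinom"` or `"none"` (expected counts,
#'   rounded).
#' @param nbSize Negative-binomial size (dispersion) when
#'   `noise = "nbinom"`.
#' @param senseMeanLog,senseSdLog Log-normal parameters of baseline sense
#'   levels (relative RPKM units).
#' @param antisenseBackgroundRpkm Baseline antisense level of unplanted
#'   genes.
#' @param plantedBaselineRange Uniform range of planted genes' baseline
#'   antisense levels.
#' @param subsetSizes Named sizes of the planted subsets `cdk9_only`,
#'   `h2bub1_only`, `shared`, `double_only`.
#' @param singleFold Antisense fold induction by a single perturbation.
#' @param synergyFactor Double-mutant fold = `synergyFactor * singleFold`
#'   for planted single-perturbation genes.
#' @param doubleOnlyFold Fold for `double_only` genes in the drug-treated
#'   double mutant.
#' @param intergenicFraction Fraction of each library drawn from
#'   intergenic background.
#' @param nRandomTerms,termSize Synthetic term map: number and size of
#'   random (unenriched) terms added to the planted-subset terms.
#' @return Configuration list for [simulateRnaSeq()].
#' @export
rnaSeqConfig <- function(nGenes = 2000L, nChroms = 2L,
                         geneLengthRange = c(500L, 3000L),
                         gapRange = c(800L, 1500L),
                         nonCodingFraction = 0.05,
                         readLength = 50L, depth = 1e6, replicates = 2L,
                         noise = c("poisson", "nbinom", "none"),
                         nbSize = 10,
                         senseMeanLog = log(250), senseSdLog = 0.8,
                         antisenseBackgroundRpkm = 0.05,
                         plantedBaselineRange = c(8, 20),
                         subsetSizes = c(cdk9_only = 60L, h2bub1_only = 60L,
                                         shared = 30L, double_only = 400L),
                         singleFold = 4, synergyFactor = 3,
                         doubleOnlyFold = 4,
                         intergenicFraction = 0.02,
                         nRandomTerms = 5L, termSize = 50L) {
  cfg <- list(nGenes = as.integer(nGenes), nChroms = as.integer(nChroms),
              geneLengthRange = geneLengthRange, gapRange = gapRange,
              nonCodingFraction = nonCodingFraction,
              readLength = as.integer(readLength), depth = depth,
              replicates = as.integer(replicates),
              noise = match.arg(noise), nbSize = nbSize,
              senseMeanLog = senseMeanLog, senseSdLog = senseSdLog,
              antisenseBackgroundRpkm = antisenseBackgroundRpkm,
              plantedBaselineRange = plantedBaselineRange,
              subsetSizes = subsetSizes, singleFold = singleFold,
              synergyFactor = synergyFactor,
              doubleOnlyFold = doubleOnlyFold,
              intergenicFraction = intergenicFraction,
              nRandomTerms = as.integer(nRandomTerms),
              termSize = as.integer(termSize))
  .checkRnaSeqConfig(cfg)
  cfg
}

.checkRnaSeqConfig <- function(cfg) {
  if (cfg$depth <= 0) stop("library depth must be positive")
  if (sum(cfg$subsetSizes) > cfg$nGenes)
    stop("planted subset sizes exceed the number of genes")
  if (!all(names(cfg$subsetSizes) ==
           c("cdk9_only", "h2bub1_only", "shared", "double_only")))
    stop("subsetSizes must be named cdk9_only, h2bub1_only, shared, double_only")
  if (cfg$singleFold < 0 || cfg$synergyFactor < 0 || cfg$doubleOnlyFold < 0)
    stop("fold effects must be non-negative")
  invisible(cfg)
}

## Per-condition antisense fold for each gene given its planted subset.
## The kinase mutant needs the inhibitor; the histone mutant is
## constitutive; the drug-treated double mutant induces every planted
## subset, with the synergy factor applied to single-perturbation genes.
.antisenseFold <- function(subset, strain, treatment, cfg) {
  fold <- rep(1, length(subset))
  s1 <- cfg$singleFold
  if (strain == "cdk9as" && treatment == "3MBPP1")
    fold[subset %in% c("cdk9_only", "shared")] <- s1
  if (strain == "htb1K119R")
    fold[subset %in% c("h2bub1_only", "shared")] <- s1
  if (strain == "cdk9as_htb1K119R") {
    if (treatment == "DMSO") {
      fold[subset %in% c("h2bub1_only", "shared")] <- s1
    } else {
      fold[subset %in% c("cdk9_only", "h2bub1_only", "shared")] <-
        s1 * cfg$synergyFactor
      fold[subset == "double_only"] <- cfg$doubleOnlyFold
    }
  }
  fold
}

.makeToyAnnotation <- function(cfg) {
  n <- cfg$nGenes
  lens <- floor(runif(n, cfg$geneLengthRange[1], cfg$geneLengthRange[2] + 1))
  gaps <- floor(runif(n + cfg$nChroms, cfg$gapRange[1], cfg$gapRange[2] + 1))
  chromOf <- rep(seq_len(cfg$nChroms), length.out = n)
  chromOf <- sort(chromOf)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  biotype <- rep("protein_coding", n)
  if (cfg$nonCodingFraction > 0) {
    nnc <- round(cfg$nonCodingFraction * n)
    biotype[sample.int(n, nnc)] <- "non_coding"
  }
  starts <- integer(n); ends <- integer(n)
  sizes <- integer(cfg$nChroms)
  gi <- 1L
  for (ch in seq_len(cfg$nChroms)) {
    pos <- 1L
    for (i in which(chromOf == ch)) {
      pos <- pos + gaps[gi]; gi <- gi + 1L
      starts[i] <- pos
      ends[i] <- pos + lens[i] - 1L
      pos <- ends[i] + 1L
    }
    sizes[ch] <- pos + gaps[gi] - 1L; gi <- gi + 1L
  }
  chromNames <- sprintf("chr%s", utils::as.roman(seq_len(cfg$nChroms)))
  gr <- GRanges(chromNames[chromOf], IRanges(starts, ends),
                strand = strands,
                gene_id = sprintf("gene%04d", seq_len(n)),
                biotype = biotype)
  GenomeAnnotation(gr, setNames(sizes, chromNames))
}

.drawCounts <- function(mu, cfg) {
  switch(cfg$noise,
         poisson = rpois(length(mu), mu),
         nbinom = rnbinom(length(mu), mu = mu, size = cfg$nbSize),
         none = round(mu))
}

## Uniform (or, noise-free, evenly spaced) read starts within [lo, hi].
.readStarts <- function(lo, hi, counts, noiseFree) {
  span <- hi - lo + 1L
  lo <- rep(lo, counts); span <- rep(span, counts)
  u <- if (noiseFree) {
    unlist(lapply(counts[counts > 0L],
                  function(k) (seq_len(k) - 0.5) / k), use.names = FALSE)
  } else runif(length(lo))
  as.integer(lo + floor(u * span))
}

#' Simulate stranded RNA-seq libraries with planted antisense induction
#'
#' Generates the toy annotation, the full strain x treatment x replicate
#' design, one stranded read set (`GRanges` of `readLength`-bp intervals)
#' per library, the planted truth table, and a synthetic term map. A
#' read's strand is the transcript strand (the classifier's convention
#' flag handles dUTP-style libraries). Identical seed and configuration
#' give identical output.
#'
#' The truth table has one row per gene: `gene_id`, `subset`,
#' `baseline_sense_rpkm` and `baseline_antisense_rpkm` (expected RPKM in
#' the wild-type library), and one `fold_<strain>_<treatment>` column per
#' condition.
#'
#' @param config From [rnaSeqConfig()].
#' @param seed Integer seed.
#' @return A [SyntheticDataset-class] (RNA part; empty `chip` slot).
#' @export
simulateRnaSeq <- function(config = rnaSeqConfig(), seed = 1L) {
  cfg <- .checkRnaSeqConfig(config)
  set.seed(seed)
  ann <- .makeToyAnnotation(cfg)
  g <- genes(ann)
  n <- length(g)
  glen <- width(g)
  pc <- which(mcols(g)$biotype == "protein_coding")

  subset <- rep("none", n)
  pool <- sample(pc)  # random order, then carve disjoint subsets
  off <- 0L
  for (nm in names(cfg$subsetSizes)) {
    k <- cfg$subsetSizes[[nm]]
    subset[pool[off + seq_len(k)]] <- nm
    off <- off + k
  }

  senseLevel <- rlnorm(n, cfg$senseMeanLog, cfg$senseSdLog)
  antiBase <- rep(cfg$antisenseBackgroundRpkm, n)
  # antisense is defined over protein-coding genes only; non-coding loci
  # get no antisense background
  antiBase[mcols(g)$biotype == "non_coding"] <- 0
  planted <- subset != "none"
  antiBase[planted] <- runif(sum(planted), cfg$plantedBaselineRange[1],
                             cfg$plantedBaselineRange[2])

  win <- intergenicWindows(ann, minWidth = cfg$readLength)
  wlen <- width(win)

  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        treatment = .TREATMENTS, strain = .STRAINS,
                        stringsAsFactors = FALSE)
  design <- design[, c("strain", "treatment", "replicate")]
  design$sample <- sprintf("%s_%s_rep%d", design$strain, design$treatment,
                           design$replicate)

  wS <- senseLevel * glen
  igShare <- cfg$intergenicFraction
  reads <- vector("list", nrow(design))
  names(reads) <- design$sample
  noiseFree <- cfg$noise == "none"
  for (i in seq_len(nrow(design))) {
    fold <- .antisenseFold(subset, design$strain[i], design$treatment[i], cfg)
    wA <- antiBase * fold * glen
    wI_tot <- igShare / (1 - igShare) * (sum(wS) + sum(wA))
    wI <- wI_tot * wlen / sum(wlen)
    wAll <- sum(wS) + sum(wA) + sum(wI)
    muS <- cfg$depth * wS / wAll
    muA <- cfg$depth * wA / wAll
    muI <- cfg$depth * wI / wAll
    cS <- .drawCounts(muS, cfg); cA <- .drawCounts(muA, cfg)
    cI <- .drawCounts(muI, cfg)
    hiG <- end(g) - cfg$readLength + 1L
    chrG <- as.character(seqnames(g))
    strG <- as.character(strand(g))
    chrW <- as.character(seqnames(win))
    hiW <- end(win) - cfg$readLength + 1L
    startS <- .readStarts(start(g), hiG, cS, noiseFree)
    startA <- .readStarts(start(g), hiG, cA, noiseFree)
    startI <- .readStarts(start(win), hiW, cI, noiseFree)
    strI <- rep_len(c("+", "-"), length(startI))
    if (!noiseFree && length(startI))
      strI <- sample(c("+", "-"), length(startI), replace = TRUE)
    rd <- GRanges(
      c(rep(chrG, cS), rep(chrG, cA), rep(chrW, cI)),
      IRanges(c(startS, startA, startI), width = cfg$readLength),
      strand = c(rep(strG, cS),
                 rep(ifelse(strG == "+", "-", "+"), cA), strI))
    GenomeInfoDb::seqlevels(rd) <- names(chromSizes(ann))
    seqlengths(rd) <- chromSizes(ann)
    reads[[i]] <- rd
  }

  # expected RPKM on the realized scale, wild-type condition
  foldWT <- .antisenseFold(subset, "WT", "DMSO", cfg)
  wA_wt <- antiBase * foldWT * glen
  wI_wt <- igShare / (1 - igShare) * (sum(wS) + sum(wA_wt))
  wAll_wt <- sum(wS) + sum(wA_wt) + wI_wt
  truth <- data.frame(gene_id = mcols(g)$gene_id, subset = subset,
                      baseline_sense_rpkm = senseLevel * 1e9 / wAll_wt,
                      baseline_antisense_rpkm = antiBase * 1e9 / wAll_wt,
                      stringsAsFactors = FALSE)
  for (st in .STRAINS) for (tr in .TREATMENTS)
    truth[[sprintf("fold_%s_%s", st, tr)]] <-
      .antisenseFold(subset, st, tr, cfg)

  termMap <- .makeTermMap(mcols(g)$gene_id[pc], subset[pc], cfg)

  new("SyntheticDataset", annotation = ann, design = design,
      reads = reads, chip = list(), truth = truth, termMap = termMap,
      seed = as.integer(seed), config = list(rnaseq = cfg))
}

## Planted subsets become "terms" (maximally enriched by construction);
## random terms of fixed size provide the null background.
.makeTermMap <- function(pcIds, pcSubset, cfg) {
  maps <- list()
  for (nm in unique(pcSubset[pcSubset != "none"]))
    maps[[length(maps) + 1L]] <-
      data.frame(term = paste0("planted_", nm),
                 gene_id = pcIds[pcSubset == nm], stringsAsFactors = FALSE)
  for (k in seq_len(cfg$nRandomTerms))
    maps[[length(maps) + 1L]] <-
      data.frame(term = sprintf("random_term_%02d", k),
                 gene_id = sample(pcIds, min(cfg$termSize, length(pcIds))),
                 stringsAsFactors = FALSE)
  do.call(rbind, maps)
}
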