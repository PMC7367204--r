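# Independent oracles and small fixture builders, kept deliberately
# naive: plain loops over every feature, no interval index.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# Random annotation with engineered overlaps: genes are placed freely
# (uniform starts), so same- and opposite-strand overlaps of every
# flavour arise naturally.
randomAnnotation <- function(nGenes, chromLen = 50000L, nChroms = 2L) {
  chroms <- sprintf("chr%d", seq_len(nChroms))
  chrom <- sample(chroms, nGenes, replace = TRUE)
  len <- sample(200:2000, nGenes, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chromLen - l, 1L), integer(1))
  gr <- GRanges(chrom, IRanges(start, start + len - 1L),
                strand = sample(c("+", "-"), nGenes, TRUE),
                gene_id = sprintf("g%03d", seq_len(nGenes)),
                biotype = sample(c("protein_coding", "non_coding"), nGenes,
                                 TRUE, prob = c(0.9, 0.1)))
  GenomeAnnotation(gr, setNames(rep(chromLen, nChroms), chroms))
}

randomReads <- function(n, annotation, readLen = 50L) {
  cs <- chromSizes(annotation)
  chrom <- sample(names(cs), n, replace = TRUE)
  start <- vapply(chrom, function(ch) sample.int(cs[[ch]] - readLen, 1L),
                  integer(1))
  GRanges(chrom, IRanges(start, width = readLen),
          strand = sample(c("+", "-"), n, TRUE))
}

# Brute-force read classifier: enumerate every gene for every read.
bruteClassify <- function(reads, annotation,
                          convention = "read_is_transcript_strand",
                          antisenseBiotypes = "protein_coding") {
  g <- genes(annotation)
  gid <- mcols(g)$gene_id
  bt <- mcols(g)$biotype
  out <- data.frame(category = character(length(reads)),
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    rchr <- as.character(seqnames(reads))[i]
    rs <- start(reads)[i]; re <- end(reads)[i]
    eff <- as.character(strand(reads))[i]
    if (convention == "read_is_opposite") eff <- setdiff(c("+", "-"), eff)
    ovw <- pmin(re, end(g)) - pmax(rs, start(g)) + 1L
    hit <- as.character(seqnames(g)) == rchr & ovw > 0L
    sameHit <- hit & as.character(strand(g)) == eff
    oppHit <- hit & as.character(strand(g)) != eff & bt %in% antisenseBiotypes
    if (any(sameHit)) {
      idx <- which(sameHit)
      idx <- idx[order(-ovw[idx], gid[idx])][1]
      out$category[i] <- "sense"; out$gene_id[i] <- gid[idx]
    } else if (sum(oppHit) == 1L) {
      out$category[i] <- "antisense"; out$gene_id[i] <- gid[which(oppHit)]
    } else if (sum(oppHit) >= 2L) {
      out$category[i] <- "discarded"
    } else {
      out$category[i] <- "intergenic"
    }
  }
  out
}

# Expression-table builder for statistics tests (bypasses counting).
makeExpr <- function(rpkm, class = "antisense", length = 1000L,
                     ids = sprintf("g%03d", seq_along(rpkm))) {
  new("ExpressionTable",
      table = data.frame(feature_id = ids, class = class,
                         length = length, rpkm = rpkm,
                         stringsAsFactors = FALSE),
      nReplicates = 1L, samples = "test")
}

constantTrack <- function(value, chromSizes, binSize = 1L) {
  CoverageTrack(lapply(chromSizes, function(l)
    rep(value, ceiling(l / binSize))), binSize, "const")
}

# Unplanted tiny configuration for structural tests.
tinyRnaConfig <- function(nGenes, depth, ...) {
  rnaSeqConfig(nGenes = nGenes, depth = depth,
               subsetSizes = c(cdk9_only = 0L, h2bub1_only = 0L,
                               shared = 0L, double_only = 0L), ...)
}

# A small planted-design configuration used by several tests.
smallRnaConfig <- function(...) {
  rnaSeqConfig(nGenes = 200L, depth = 5e4,
               subsetSizes = c(cdk9_only = 10L, h2bub1_only = 10L,
                               shared = 6L, double_only = 20L), ...)
}

# Quantify selected samples of a synthetic dataset and average
# replicates per condition.
quantifyConditions <- function(ds, conditions) {
  ann <- datasetAnnotation(ds)
  design <- datasetDesign(ds)
  win <- intergenicWindows(ann)
  out <- list()
  for (key in conditions) {
    smps <- design$sample[paste(design$strain, design$treatment,
                                sep = "_") == key]
    tabs <- lapply(smps, function(s)
      rpkmNormalize(countReads(datasetReads(ds, s), ann, s, windows = win),
                    ann))
    out[[key]] <- averageReplicates(tabs)
  }
  out
}
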