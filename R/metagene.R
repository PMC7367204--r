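## Metagene matrices, profiles, clustering, and the CPS trough statistic.
##
## Rows are always oriented 5' -> 3' along the gene: for minus-strand
## genes the per-base window is read right-to-left before binning, so
## reversing a gene's strand and mirroring the track leaves its row
## unchanged.

## Per-base values of `track` at genomic positions `pos` (1-based).
.trackAt <- function(track, chrom, pos) {
  v <- trackValues(track)[[chrom]]
  if (is.null(v)) stop("track lacks chromosome: ", chrom)
  v[(pos - 1L) %/% trackBinSize(track) + 1L]
}

.binMeans <- function(x, nBins) {
  idx <- floor((seq_along(x) - 1L) * nBins / length(x)) + 1L
  as.numeric(tapply(x, idx, mean))
}

#' Anchored metagene matrix (TSS or CPS)
#'
#' Row `g` holds mean signal per `binSize`-bp bin over the window
#' `[anchor - upstream, anchor + downstream)` in the gene's 5' -> 3'
#' orientation (offset 0 = the anchor base). Genes whose window would
#' leave the chromosome are dropped with a message rather than padded.
#'
#' @param track A [CoverageTrack-class].
#' @param annotation A [GenomeAnnotation-class] (or `GRanges` with
#'   `gene_id`).
#' @param anchor `"TSS"` or `"CPS"`.
#' @param upstream,downstream Window extent in bp (total
#'   `upstream + downstream`, a multiple of `binSize`).
#' @param binSize Bin width in bp (default 50).
#' @param geneIds Optional subset of gene ids to use.
#' @return A [MetageneMatrix-class].
#' @export
anchoredMatrix <- function(track, annotation, anchor = c("TSS", "CPS"),
                           upstream = 500L, downstream = 500L,
                           binSize = 50L, geneIds = NULL) {
  anchor <- match.arg(anchor)
  g <- if (is(annotation, "GenomeAnnotation")) genes(annotation)
       else annotation
  if (!is.null(geneIds)) g <- g[mcols(g)$gene_id %in% geneIds]
  if (!length(g)) stop("empty gene list")
  winLen <- upstream + downstream
  if (winLen %% binSize != 0)
    stop("upstream + downstream must be a multiple of binSize")
  anchorPos <- if (anchor == "TSS") .tssPositions(g) else .cpsPositions(g)
  dir <- ifelse(as.character(strand(g)) == "+", 1L, -1L)
  chrom <- as.character(seqnames(g))
  chromLen <- vapply(trackValues(track), length,
                     integer(1)) * trackBinSize(track)
  lo <- anchorPos - dir * upstream
  hi <- anchorPos + dir * (downstream - 1L)
  ok <- pmin(lo, hi) >= 1L & pmax(lo, hi) <= chromLen[chrom]
  if (!all(ok))
    message(sum(!ok), " gene(s) dropped: window exceeds chromosome bounds")
  g <- g[ok]; anchorPos <- anchorPos[ok]; dir <- dir[ok]; chrom <- chrom[ok]
  if (!length(g)) stop("no genes left after bounds filtering")
  offsets <- seq.int(-upstream, downstream - 1L)
  rows <- t(vapply(seq_along(g), function(i) {
    vals <- .trackAt(track, chrom[i], anchorPos[i] + dir[i] * offsets)
    .binMeans(vals, winLen %/% binSize)
  }, numeric(winLen %/% binSize)))
  rownames(rows) <- mcols(g)$gene_id
  new("MetageneMatrix", values = rows, anchor = anchor,
      upstream = as.integer(upstream), downstream = as.integer(downstream),
      binSize = as.integer(binSize), nBodyBins = 0L)
}

#' Gene-scaled metagene matrix
#'
#' The gene body from `fromTss` bp downstream of the TSS to `beforeCps`
#' bp upstream of the CPS is resampled into `nBodyBins` equal-width bins
#' (per-base means), so bodies of different length align; optional
#' unscaled flanks (`upstream` bp before the TSS, `downstream` bp after
#' the CPS, binned at `binSize`) are concatenated. Genes whose trimmed
#' body is shorter than `nBodyBins` bp, or whose window leaves the
#' chromosome, are dropped with a message.
#'
#' @inheritParams anchoredMatrix
#' @param nBodyBins Number of scaled body bins (default 100).
#' @param fromTss,beforeCps Body trim offsets in bp (default 200/200).
#' @param upstream,downstream Unscaled flank extents in bp (default 0).
#' @return A [MetageneMatrix-class] with `anchor = "scaled"`.
#' @export
scaledMatrix <- function(track, annotation, nBodyBins = 100L,
                         fromTss = 200L, beforeCps = 200L,
                         upstream = 0L, downstream = 0L, binSize = 50L,
                         geneIds = NULL) {
  g <- if (is(annotation, "GenomeAnnotation")) genes(annotation)
       else annotation
  if (!is.null(geneIds)) g <- g[mcols(g)$gene_id %in% geneIds]
  if (!length(g)) stop("empty gene list")
  if ((upstream + downstream) > 0 && (upstream %% binSize != 0 ||
                                      downstream %% binSize != 0))
    stop("flank extents must be multiples of binSize")
  tss <- .tssPositions(g); cps <- .cpsPositions(g)
  dir <- ifelse(as.character(strand(g)) == "+", 1L, -1L)
  chrom <- as.character(seqnames(g))
  chromLen <- vapply(trackValues(track), length,
                     integer(1)) * trackBinSize(track)
  bodyLen <- width(g) - fromTss - beforeCps
  lo <- tss - dir * upstream
  hi <- cps + dir * downstream
  ok <- bodyLen >= nBodyBins &
    pmin(lo, hi) >= 1L & pmax(lo, hi) <= chromLen[chrom]
  if (!all(ok))
    message(sum(!ok),
            " gene(s) dropped: body too short or window out of bounds")
  if (!any(ok)) stop("all genes too short for the requested scaling")
  g <- g[ok]; tss <- tss[ok]; cps <- cps[ok]; dir <- dir[ok]
  chrom <- chrom[ok]; bodyLen <- bodyLen[ok]
  nFlankUp <- upstream %/% binSize
  nFlankDn <- downstream %/% binSize
  nc <- nFlankUp + nBodyBins + nFlankDn
  rows <- t(vapply(seq_along(g), function(i) {
    row <- numeric(0)
    if (nFlankUp > 0) {
      off <- seq.int(-upstream, -1L)
      row <- c(row, .binMeans(.trackAt(track, chrom[i],
                                       tss[i] + dir[i] * off), nFlankUp))
    }
    bodyOff <- seq.int(fromTss, fromTss + bodyLen[i] - 1L)
    row <- c(row, .binMeans(.trackAt(track, chrom[i],
                                     tss[i] + dir[i] * bodyOff), nBodyBins))
    if (nFlankDn > 0) {
      off <- seq.int(1L, downstream)
      row <- c(row, .binMeans(.trackAt(track, chrom[i],
                                       cps[i] + dir[i] * off), nFlankDn))
    }
    row
  }, numeric(nc)))
  rownames(rows) <- mcols(g)$gene_id
  new("MetageneMatrix", values = rows, anchor = "scaled",
      upstream = as.integer(upstream), downstream = as.integer(downstream),
      binSize = as.integer(binSize), nBodyBins = as.integer(nBodyBins))
}

#' Column-wise metagene profile
#'
#' @param matrix A [MetageneMatrix-class].
#' @param stat `"mean"` or `"median"`; `NA` cells are excluded. A column
#'   with no valid cells yields `NA` with a warning.
#' @return Numeric vector, one value per bin.
#' @export
metaProfile <- function(matrix, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  m <- as.matrix(matrix)
  if (!nrow(m)) stop("empty metagene matrix")
  f <- if (stat == "mean") function(x) mean(x, na.rm = TRUE)
       else function(x) median(x, na.rm = TRUE)
  out <- apply(m, 2, f)
  if (any(!is.finite(out))) {
    warning("profile has bins with no valid cells")
    out[!is.finite(out)] <- NA_real_
  }
  out
}

#' Order genes by a score and slice into clusters
#'
#' Genes are sorted by score, high to low (ties broken by gene id for
#' determinism). `fixed_size` mode cuts consecutive blocks of
#' `k` genes (the last block may be smaller); `quantile` mode makes `k`
#' groups whose sizes differ by at most one.
#'
#' @param scores Named numeric vector (gene id -> score), all finite.
#' @param mode `"fixed_size"` or `"quantile"`.
#' @param k Block size (`fixed_size`) or number of groups (`quantile`).
#' @return `data.frame` with `gene_id`, `score`, `cluster` (1 = highest
#'   scores), in cluster order.
#' @export
clusterGenes <- function(scores, mode = c("fixed_size", "quantile"), k) {
  mode <- match.arg(mode)
  if (!length(scores)) stop("empty score vector")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (k < 1) stop("k must be >= 1")
  o <- order(-scores, names(scores))
  n <- length(scores)
  cluster <- if (mode == "fixed_size") {
    (seq_len(n) - 1L) %/% as.integer(k) + 1L
  } else {
    as.integer(ceiling(seq_len(n) * k / n))
  }
  data.frame(gene_id = names(scores)[o], score = unname(scores[o]),
             cluster = cluster, stringsAsFactors = FALSE)
}

#' Trough depth statistic around an anchor
#'
#' Dimensionless trough depth of a profile:
#' `min(profile[anchor - flank .. anchor + flank]) / mean(shoulders)`,
#' the shoulders being the two window-edge bins. A flat profile gives
#' 1.0; a 60%-deep trough gives about 0.4. The flank must be wide enough
#' that the window edges sit on the shoulders, outside the trough.
#'
#' @param profile Numeric profile vector.
#' @param anchorBin Index of the anchor bin.
#' @param flankBins Half-window width in bins.
#' @return The trough statistic.
#' @export
troughStatistic <- function(profile, anchorBin, flankBins) {
  lo <- anchorBin - flankBins; hi <- anchorBin + flankBins
  if (lo < 1 || hi > length(profile))
    stop("trough window exceeds profile bounds")
  shoulders <- mean(c(profile[lo], profile[hi]))
  if (!is.finite(shoulders) || shoulders == 0)
    stop("zero or undefined shoulder mean")
  min(profile[lo:hi], na.rm = TRUE) / shoulders
}

#' Mean occupancy score per gene from a track
#'
#' Mean signal over each gene's body — the ordering statistic for
#' occupancy-based clustering.
#'
#' @param track A [CoverageTrack-class].
#' @param annotation A [GenomeAnnotation-class].
#' @return Named numeric vector (gene id -> mean signal).
#' @export
geneOccupancy <- function(track, annotation) {
  g <- genes(annotation)
  out <- vapply(seq_along(g), function(i) {
    mean(.trackAt(track, as.character(seqnames(g))[i],
                  seq.int(start(g)[i], end(g)[i])))
  }, numeric(1))
  setNames(out, mcols(g)$gene_id)
}
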