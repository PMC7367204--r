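## Spike-in normalization and ratio tracks.
##
## Spike-in chromatin added in fixed proportion to every sample reports
## on IP efficiency and sequencing depth jointly: IP signal is rescaled
## by the spike recovery of the matched input relative to the IP,
##   scale = input_spike_reads / ip_spike_reads,
## so equal spike recovery gives a factor of 1 and scaling a sample's
## target and spike reads together cancels exactly (up to the
## pseudocount). A reference-anchored alternative for cross-sample
## comparisons is available via `spikeScaleToReference()`.

#' Spike-in scale factor for an IP/input pair
#'
#' @param ipSpikeReads,inputSpikeReads Positive spike-in read counts for
#'   the IP and input libraries.
#' @return `inputSpikeReads / ipSpikeReads`.
#' @export
spikeScale <- function(ipSpikeReads, inputSpikeReads) {
  if (ipSpikeReads <= 0 || inputSpikeReads <= 0)
    stop("spike-in read counts must be positive; signal is un-normalizable")
  inputSpikeReads / ipSpikeReads
}

#' Reference-anchored spike scale for cross-sample comparison
#'
#' `referenceSpikeReads / sampleSpikeReads` on IP libraries, for
#' comparing IP signals across samples against a common reference.
#'
#' @param sampleSpikeReads,referenceSpikeReads Positive IP spike counts.
#' @return The multiplicative factor for the sample's IP signal.
#' @export
spikeScaleToReference <- function(sampleSpikeReads, referenceSpikeReads) {
  if (sampleSpikeReads <= 0 || referenceSpikeReads <= 0)
    stop("spike-in read counts must be positive")
  referenceSpikeReads / sampleSpikeReads
}

.checkBins <- function(a, b) {
  if (trackBinSize(a) != trackBinSize(b))
    stop("tracks have different bin sizes")
  va <- trackValues(a); vb <- trackValues(b)
  if (!identical(names(va), names(vb)) ||
      !identical(lengths(va), lengths(vb)))
    stop("tracks have mismatched chromosomes/bins")
  invisible(TRUE)
}

#' Spike-in-normalized ChIP signal
#'
#' Per bin: `scale * (ip + pseudocount) / (input + pseudocount)`, with
#' `scale` from [spikeScale()]. Bins where the input falls below
#' `inputFloor` are masked to `NA` to avoid spurious extreme ratios.
#'
#' @param ip,input [CoverageTrack-class] objects with matching bins.
#' @param ipSpikeReads,inputSpikeReads Spike-in read counts.
#' @param pseudocount Added to both tracks (default 1 coverage unit).
#' @param inputFloor Minimum input coverage for a reported bin
#'   (default 0 = no masking).
#' @return A [CoverageTrack-class] of normalized signal.
#' @export
normalizedSignal <- function(ip, input, ipSpikeReads, inputSpikeReads,
                             pseudocount = 1, inputFloor = 0) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  .checkBins(ip, input)
  sf <- spikeScale(ipSpikeReads, inputSpikeReads)
  vi <- trackValues(ip); vn <- trackValues(input)
  vals <- Map(function(a, b) {
    out <- sf * (a + pseudocount) / (b + pseudocount)
    if (inputFloor > 0) out[b < inputFloor] <- NA_real_
    out
  }, vi, vn)
  CoverageTrack(vals, trackBinSize(ip),
                paste0(trackLabel(ip), "_norm"))
}

#' Ratio track between two signals
#'
#' Per bin `(num + pseudocount) / (den + pseudocount)`, log2-transformed
#' when `mode = "log2"`.
#'
#' @param numerator,denominator [CoverageTrack-class] objects with
#'   matching bins.
#' @param mode `"ratio"` or `"log2"`.
#' @param pseudocount Added to both tracks (default 1).
#' @return A [CoverageTrack-class].
#' @export
ratioTrack <- function(numerator, denominator, mode = c("ratio", "log2"),
                       pseudocount = 1) {
  mode <- match.arg(mode)
  .checkBins(numerator, denominator)
  vn <- trackValues(numerator); vd <- trackValues(denominator)
  vals <- Map(function(a, b) {
    r <- (a + pseudocount) / (b + pseudocount)
    if (mode == "log2") log2(r) else r
  }, vn, vd)
  CoverageTrack(vals, trackBinSize(numerator),
                sprintf("%s_over_%s%s", trackLabel(numerator),
                        trackLabel(denominator),
                        if (mode == "log2") "_log2" else ""))
}

#' Rebin a track to a coarser resolution
#'
#' Means of consecutive `factor`-bin blocks (a trailing partial block is
#' averaged over its actual length).
#'
#' @param track A [CoverageTrack-class].
#' @param factor Integer number of old bins per new bin.
#' @return A [CoverageTrack-class] with `binSize * factor`.
#' @export
binTrack <- function(track, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  vals <- lapply(trackValues(track), function(v) {
    idx <- (seq_along(v) - 1L) %/% factor
    as.numeric(tapply(v, idx, mean))
  })
  CoverageTrack(vals, trackBinSize(track) * factor, trackLabel(track))
}

## bedGraph I/O: tracks are written as run-compressed intervals and read
## back into per-base (or per-bin) vectors.

#' Write a CoverageTrack as bedGraph
#'
#' @param track A [CoverageTrack-class].
#' @param path Output path.
#' @param chromSizes Optional named lengths (defaults to track extents).
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(track, path, chromSizes = NULL) {
  bs <- trackBinSize(track)
  chromV <- character(); startV <- integer(); endV <- integer()
  scoreV <- numeric()
  for (chrom in names(trackValues(track))) {
    r <- Rle(trackValues(track)[[chrom]])
    ends <- cumsum(runLength(r)) * bs
    chromV <- c(chromV, rep(chrom, length(ends)))
    startV <- c(startV, ends - runLength(r) * bs + 1L)
    endV <- c(endV, ends)
    scoreV <- c(scoreV, runValue(r))
  }
  gr <- GRanges(chromV, IRanges(startV, endV), score = scoreV)
  export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a CoverageTrack
#'
#' Values are expanded to per-`binSize` vectors over `chromSizes`;
#' uncovered positions are 0.
#'
#' @param path bedGraph path.
#' @param chromSizes Named chromosome lengths.
#' @param binSize Bin size the file was written at (default 1).
#' @param label Track label.
#' @return A [CoverageTrack-class].
#' @export
readBedGraph <- function(path, chromSizes, binSize = 1L, label = "") {
  gr <- import(path, format = "bedGraph")
  binSize <- as.integer(binSize)
  vals <- lapply(names(chromSizes), function(chrom) {
    n <- as.integer(ceiling(chromSizes[[chrom]] / binSize))
    v <- numeric(n)
    sel <- as.character(seqnames(gr)) == chrom
    if (any(sel)) {
      s <- (start(gr)[sel] - 1L) %/% binSize + 1L
      e <- (end(gr)[sel] - 1L) %/% binSize + 1L
      sc <- gr$score[sel]
      contiguous <- length(s) && s[1] == 1L && e[length(e)] == n &&
        (length(s) == 1L || all(s[-1] == e[-length(e)] + 1L))
      if (contiguous) {
        v <- rep(sc, e - s + 1L)
      } else {
        for (i in seq_along(s)) v[s[i]:e[i]] <- sc[i]
      }
    }
    v
  })
  names(vals) <- names(chromSizes)
  CoverageTrack(vals, binSize, label)
}
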