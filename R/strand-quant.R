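## Stranded read classification and RPKM quantification.
##
## Classification rule (per read, after resolving the library convention
## to an effective transcript strand):
##   1. overlaps >= 1 gene on its own strand      -> sense, to the gene
##      with the largest overlap (ties: lexicographically smallest id);
##   2. else overlaps exactly one opposite-strand
##      eligible gene                             -> antisense to it;
##   3. else overlaps >= 2 opposite-strand genes  -> discarded;
##   4. else                                      -> intergenic.
## Same-strand assignment takes precedence so that sense reads of
## overlapping convergent gene pairs do not inflate antisense counts.

#' Classify stranded reads as sense / antisense / intergenic
#'
#' Applies the classification rule above to every read. `convention`
#' states whether the sequenced read strand is the transcript strand
#' (`"read_is_transcript_strand"`, the default) or its reverse complement
#' (`"read_is_opposite"`, the dUTP convention). Reads antisense to more
#' than one gene are ambiguous and discarded. By default only
#' protein-coding genes can host antisense calls
#' (`antisenseBiotypes = "protein_coding"`).
#'
#' @param reads `GRanges` of read intervals with strand `+`/`-`.
#' @param annotation A [GenomeAnnotation-class].
#' @param convention Read-strand convention (see above).
#' @param minOverlap Minimum overlap in bp for a read-gene hit (default 1).
#' @param antisenseBiotypes Biotypes eligible to host antisense calls.
#' @return `data.frame` with one row per read: `category` (`sense`,
#'   `antisense`, `intergenic`, `discarded`) and `gene_id` (`NA` unless
#'   sense/antisense).
#' @export
assignReads <- function(reads, annotation,
                        convention = c("read_is_transcript_strand",
                                       "read_is_opposite"),
                        minOverlap = 1L,
                        antisenseBiotypes = "protein_coding") {
  convention <- match.arg(convention)
  cs <- chromSizes(annotation)
  rchr <- as.character(seqnames(reads))
  if (!all(rchr %in% names(cs)))
    stop("reads on unknown chromosome: ",
         paste(unique(rchr[!rchr %in% names(cs)]), collapse = ", "))
  g <- genes(annotation)
  n <- length(reads)
  eff <- as.character(strand(reads))
  if (convention == "read_is_opposite")
    eff <- ifelse(eff == "+", "-", "+")

  hits <- findOverlaps(reads, g, minoverlap = as.integer(minOverlap),
                       ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  gstr <- as.character(strand(g))[s]
  gid <- mcols(g)$gene_id[s]
  same <- eff[q] == gstr

  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)

  if (any(same)) {
    ov <- width(pintersect(ranges(reads)[q[same]], ranges(g)[s[same]]))
    qs <- q[same]; gs <- gid[same]
    o <- order(qs, -ov, gs)
    first <- !duplicated(qs[o])
    sel <- o[first]
    category[qs[sel]] <- "sense"
    gene_id[qs[sel]] <- gs[sel]
  }

  opp <- !same & mcols(g)$biotype[s] %in% antisenseBiotypes
  opp <- opp & category[q] != "sense"
  if (any(opp)) {
    qo <- q[opp]; go <- gid[opp]
    nOpp <- tabulate(qo, nbins = n)
    one <- nOpp == 1L
    if (any(one)) {
      keep <- one[qo]
      category[qo[keep]] <- "antisense"
      gene_id[qo[keep]] <- go[keep]
    }
    category[nOpp >= 2L] <- "discarded"
  }
  data.frame(category = category, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Count classified reads per gene and intergenic window
#'
#' Aggregates [assignReads()] output into a [StrandedCounts-class]
#' object. Intergenic reads are tallied into the fixed-width windows from
#' [intergenicWindows()], each read going to the window it overlaps most
#' (ties: left-most window). The conservation invariant
#' sense + antisense + intergenic + discarded = input reads holds exactly.
#'
#' @inheritParams assignReads
#' @param sample Sample name recorded in the result.
#' @param windows Optional precomputed intergenic windows (`GRanges`).
#' @param windowWidth Window width passed to [intergenicWindows()].
#' @return A [StrandedCounts-class] object.
#' @export
countReads <- function(reads, annotation, sample = "sample",
                       convention = c("read_is_transcript_strand",
                                      "read_is_opposite"),
                       minOverlap = 1L,
                       antisenseBiotypes = "protein_coding",
                       windows = NULL, windowWidth = 500L) {
  convention <- match.arg(convention)
  asg <- assignReads(reads, annotation, convention, minOverlap,
                     antisenseBiotypes)
  ids <- geneIds(annotation)
  idx <- match(asg$gene_id, ids)
  sense <- tabulate(idx[asg$category == "sense"], nbins = length(ids))
  anti <- tabulate(idx[asg$category == "antisense"], nbins = length(ids))
  if (is.null(windows)) windows <- intergenicWindows(annotation, windowWidth)
  wid <- if (length(windows)) mcols(windows)$window_id else character()
  igCounts <- integer(length(wid))
  igReads <- which(asg$category == "intergenic")
  unbinned <- 0L
  if (length(igReads) && length(windows)) {
    h <- findOverlaps(reads[igReads], windows, ignore.strand = TRUE)
    if (length(h)) {
      ov <- width(pintersect(ranges(reads)[igReads][queryHits(h)],
                             ranges(windows)[subjectHits(h)]))
      o <- order(queryHits(h), -ov, subjectHits(h))
      sel <- o[!duplicated(queryHits(h)[o])]
      igCounts <- tabulate(subjectHits(h)[sel], nbins = length(wid))
    }
    unbinned <- length(igReads) - sum(igCounts)
  } else {
    unbinned <- length(igReads)
  }
  new("StrandedCounts", sample = sample, geneIds = ids,
      sense = as.integer(sense), antisense = as.integer(anti),
      intergenicIds = wid, intergenic = as.integer(igCounts),
      intergenicUnbinned = as.integer(unbinned),
      discarded = sum(asg$category == "discarded"),
      nReads = length(reads))
}

#' RPKM-normalize stranded counts
#'
#' `rpkm = count * 1e9 / (length_bp * library_size)`, computed separately
#' for the sense and antisense counts of every gene and for each
#' intergenic window. The library size is the sample's assigned read
#' total (sense + antisense + intergenic) by default; discarded reads are
#' ambiguous signal, not expression, and are excluded unless
#' `librarySize = "all"`.
#'
#' @param counts A [StrandedCounts-class].
#' @param annotation The matching [GenomeAnnotation-class].
#' @param librarySize `"assigned"` (default) or `"all"`.
#' @param windowWidth Intergenic window width used when counting (must
#'   match the [countReads()] call).
#' @return An [ExpressionTable-class] (single library).
#' @export
rpkmNormalize <- function(counts, annotation,
                          librarySize = c("assigned", "all"),
                          windowWidth = 500L) {
  sizeDef <- match.arg(librarySize)
  lib <- as.numeric(librarySize(counts, sizeDef))  # avoid integer overflow
  if (lib <= 0) stop("library size is zero; cannot compute RPKM")
  if (!identical(counts@geneIds, geneIds(annotation)))
    stop("counts and annotation gene sets differ")
  glen <- width(genes(annotation))
  wlen <- integer(0)
  if (length(counts@intergenicIds)) {
    win <- intergenicWindows(annotation, windowWidth)
    wlen <- width(win)[match(counts@intergenicIds, mcols(win)$window_id)]
    if (anyNA(wlen)) stop("intergenic window ids do not match annotation")
  }
  rpkm <- function(cnt, len) cnt * 1e9 / (len * lib)
  tab <- data.frame(
    feature_id = c(counts@geneIds, counts@geneIds, counts@intergenicIds),
    class = rep(c("sense", "antisense", "intergenic"),
                c(length(counts@geneIds), length(counts@geneIds),
                  length(counts@intergenicIds))),
    length = c(glen, glen, wlen),
    rpkm = c(rpkm(counts@sense, glen), rpkm(counts@antisense, glen),
             rpkm(counts@intergenic, wlen)),
    stringsAsFactors = FALSE)
  new("ExpressionTable", table = tab, nReplicates = 1L,
      samples = counts@sample)
}

#' Average expression tables over replicates
#'
#' Arithmetic mean of per-feature RPKM across replicate libraries.
#' Feature sets must match exactly (same features, same order).
#'
#' @param tables List of [ExpressionTable-class] objects.
#' @return A replicate-averaged [ExpressionTable-class].
#' @export
averageReplicates <- function(tables) {
  if (!length(tables)) stop("no tables to average")
  ref <- exprValues(tables[[1]])
  key <- function(tab) paste(tab$feature_id, tab$class)
  for (t in tables[-1]) {
    tab <- exprValues(t)
    if (!identical(key(tab), key(ref)))
      stop("replicate tables have mismatched feature sets")
  }
  vals <- vapply(tables, function(t) exprValues(t)$rpkm,
                 numeric(nrow(ref)))
  out <- ref
  out$rpkm <- if (nrow(ref) == 1L) mean(vals) else rowMeans(vals)
  new("ExpressionTable", table = out,
      nReplicates = sum(vapply(tables, nReplicates, integer(1))),
      samples = unlist(lapply(tables, function(t) t@samples)))
}
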