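## Central S4 containers. All genomic intervals follow the Bioconductor
## convention (1-based, closed); BED input/output is converted at the
## file boundary.

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' GenomeAnnotation: gene-level annotation on a toy or real genome
#'
#' Wraps a [GenomicRanges::GRanges] of gene features (metadata columns
#' `gene_id` and `biotype`) together with chromosome lengths. Gene ids
#' must be unique, strands must be `+` or `-`, and every feature must lie
#' within its chromosome. Overlapping genes are allowed — disambiguation
#' is the read classifier's job, not the annotation's.
#'
#' @slot genes A `GRanges` with `gene_id` and `biotype` metadata columns.
#' @slot chromSizes Named integer vector of chromosome lengths.
#' @aliases GenomeAnnotation-class
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  slots = c(genes = "GRanges", chromSizes = "integer"))

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  cs <- object@chromSizes
  msg <- character()
  if (is.null(names(cs)) || any(!nzchar(names(cs))))
    msg <- c(msg, "chromSizes must be a named integer vector")
  if (!all(c("gene_id", "biotype") %in% names(mcols(g))))
    msg <- c(msg, "genes must carry 'gene_id' and 'biotype' metadata columns")
  else {
    ids <- mcols(g)$gene_id
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate gene_id: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (!all(mcols(g)$biotype %in% c("protein_coding", "non_coding")))
      msg <- c(msg, "biotype must be 'protein_coding' or 'non_coding'")
  }
  if (length(g)) {
    if (!all(as.character(strand(g)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    chr <- as.character(seqnames(g))
    if (!all(chr %in% names(cs)))
      msg <- c(msg, "every gene must lie on a chromosome listed in chromSizes")
    else if (any(start(g) < 1L) || any(end(g) > cs[chr]))
      msg <- c(msg, "gene features must fit within their chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param genes A `GRanges` with metadata columns `gene_id` and `biotype`
#'   (missing `biotype` defaults to `"protein_coding"`).
#' @param chromSizes Named integer/numeric vector of chromosome lengths;
#'   if `NULL`, taken from `seqlengths(genes)`.
#' @return A [GenomeAnnotation-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chrI", IRanges::IRanges(101, 700),
#'                              strand = "+", gene_id = "geneA")
#' ann <- GenomeAnnotation(gr, c(chrI = 10000))
#' @export
GenomeAnnotation <- function(genes, chromSizes = NULL) {
  if (is.null(chromSizes)) {
    chromSizes <- seqlengths(genes)
    if (any(is.na(chromSizes)))
      stop("chromSizes not given and seqlengths(genes) incomplete")
  }
  cs <- setNames(as.integer(chromSizes), names(chromSizes))
  chr <- as.character(seqnames(genes))
  if (!all(chr %in% names(cs)))
    stop("features on chromosomes missing from chromSizes: ",
         paste(unique(chr[!chr %in% names(cs)]), collapse = ", "))
  if (any(start(genes) < 1L) || any(end(genes) > cs[chr]))
    stop("gene features must fit within their chromosome")
  if (is.null(mcols(genes)$biotype))
    mcols(genes)$biotype <- rep("protein_coding", length(genes))
  mcols(genes) <- mcols(genes)[, c("gene_id", "biotype")]
  seqlevels(genes) <- names(cs)
  seqlengths(genes) <- cs
  new("GenomeAnnotation", genes = genes, chromSizes = cs)
}

#' StrandedCounts: per-gene sense/antisense read tallies for one sample
#'
#' Holds the outcome of classifying one sample's stranded reads against an
#' annotation: per-gene sense and antisense counts, per-intergenic-window
#' counts, the number of discarded (multi-gene antisense) reads, and the
#' input read total. The conservation invariant
#' `sum(sense) + sum(antisense) + sum(intergenic) + discarded == nReads`
#' is enforced by the validity method.
#'
#' @slot sample Sample name.
#' @slot geneIds Gene identifiers (defines row order).
#' @slot sense,antisense Integer count per gene.
#' @slot intergenicIds,intergenic Intergenic window ids and counts.
#' @slot intergenicUnbinned Intergenic-category reads falling outside
#'   every window (e.g. antisense to a biotype not eligible for
#'   antisense calling).
#' @slot discarded Number of reads discarded as ambiguous antisense.
#' @slot nReads Total input reads.
#' @aliases StrandedCounts-class
#' @exportClass StrandedCounts
setClass("StrandedCounts",
  slots = c(sample = "character", geneIds = "character",
            sense = "integer", antisense = "integer",
            intergenicIds = "character", intergenic = "integer",
            intergenicUnbinned = "integer",
            discarded = "integer", nReads = "integer"))

setValidity("StrandedCounts", function(object) {
  msg <- character()
  if (length(object@sense) != length(object@geneIds) ||
      length(object@antisense) != length(object@geneIds))
    msg <- c(msg, "sense/antisense must align with geneIds")
  if (length(object@intergenic) != length(object@intergenicIds))
    msg <- c(msg, "intergenic counts must align with intergenicIds")
  cnt <- c(object@sense, object@antisense, object@intergenic,
           object@discarded)
  if (any(cnt < 0L)) msg <- c(msg, "counts must be non-negative")
  tot <- sum(object@sense) + sum(object@antisense) +
    sum(object@intergenic) + object@intergenicUnbinned + object@discarded
  if (tot != object@nReads)
    msg <- c(msg, sprintf(
      "read conservation violated: %d classified vs %d input", tot,
      object@nReads))
  if (length(msg)) msg else TRUE
})

#' ExpressionTable: per-feature, per-strand-class RPKM values
#'
#' A long-format expression table with one row per (feature, strand class)
#' pair: gene features appear once as `sense` and once as `antisense`;
#' intergenic windows once as `intergenic`. Values are RPKM; `nReplicates`
#' records how many libraries were averaged.
#'
#' @slot table `data.frame` with columns `feature_id`, `class`, `length`,
#'   `rpkm`.
#' @slot nReplicates Number of libraries averaged into `rpkm`.
#' @slot samples Names of the contributing libraries.
#' @aliases ExpressionTable-class
#' @exportClass ExpressionTable
setClass("ExpressionTable",
  slots = c(table = "data.frame", nReplicates = "integer",
            samples = "character"))

setValidity("ExpressionTable", function(object) {
  tab <- object@table
  need <- c("feature_id", "class", "length", "rpkm")
  if (!all(need %in% names(tab)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (any(tab$rpkm < 0)) return("rpkm must be non-negative")
  if (!all(tab$class %in% c("sense", "antisense", "intergenic")))
    return("class must be sense, antisense or intergenic")
  if (object@nReplicates < 1L) return("nReplicates must be >= 1")
  TRUE
})

#' CoverageTrack: binned signal along each chromosome
#'
#' Per-chromosome numeric signal at fixed bin width (`binSize = 1` for
#' per-base tracks). Raw coverage tracks are non-negative; ratio tracks
#' (see [ratioTrack()]) may hold any real value on the log2 scale.
#'
#' @slot values Named list, one numeric vector per chromosome.
#' @slot binSize Bin width in bp.
#' @slot label Free-text label (antibody, condition, ...).
#' @aliases CoverageTrack-class
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  slots = c(values = "list", binSize = "integer", label = "character"))

setValidity("CoverageTrack", function(object) {
  if (object@binSize < 1L) return("binSize must be >= 1")
  if (is.null(names(object@values)) && length(object@values))
    return("values must be a named (per-chromosome) list")
  if (!all(vapply(object@values, is.numeric, logical(1))))
    return("values must be numeric vectors")
  TRUE
})

#' Construct a CoverageTrack
#'
#' @param values Named list of per-chromosome numeric vectors.
#' @param binSize Bin width in bp (default 1 = per-base).
#' @param label Free-text label.
#' @return A [CoverageTrack-class] object.
#' @export
CoverageTrack <- function(values, binSize = 1L, label = "") {
  new("CoverageTrack", values = values, binSize = as.integer(binSize),
      label = as.character(label))
}

#' MetageneMatrix: genes x bins signal matrix
#'
#' Rows are genes (rownames = gene ids), columns are bins ordered 5' to 3'
#' along the gene — rows of minus-strand genes are orientation-flipped at
#' construction so bin 1 is always the 5'-most bin.
#'
#' @slot values Numeric matrix, genes x bins.
#' @slot anchor `"TSS"`, `"CPS"` or `"scaled"`.
#' @slot upstream,downstream Flank extents in bp.
#' @slot binSize Bin width (flanks and anchored mode) in bp.
#' @slot nBodyBins Number of scaled body bins (0 in anchored mode).
#' @aliases MetageneMatrix-class
#' @exportClass MetageneMatrix
setClass("MetageneMatrix",
  slots = c(values = "matrix", anchor = "character",
            upstream = "integer", downstream = "integer",
            binSize = "integer", nBodyBins = "integer"))

setValidity("MetageneMatrix", function(object) {
  if (!object@anchor %in% c("TSS", "CPS", "scaled"))
    return("anchor must be TSS, CPS or scaled")
  if (is.null(rownames(object@values)) && nrow(object@values))
    return("values must have gene ids as rownames")
  TRUE
})

#' SyntheticDataset: generated genome, reads, tracks and ground truth
#'
#' Bundle produced by [simulateRnaSeq()] / [simulateChip()] /
#' [simulateDataset()]: the toy annotation, the sample design table, one
#' stranded read set (`GRanges`) per sample, ChIP IP/input tracks with
#' spike-in read counts per condition, the planted truth table, a
#' synthetic term map, and the seed + configuration that produced it all.
#'
#' @slot annotation A [GenomeAnnotation-class].
#' @slot design `data.frame` with columns `sample`, `strain`, `treatment`,
#'   `replicate`.
#' @slot reads Named list of `GRanges`, one per sample.
#' @slot chip Named list per ChIP condition: `ip`, `input`
#'   ([CoverageTrack-class]), `ipSpikeReads`, `inputSpikeReads`, and shape
#'   metadata.
#' @slot truth Planted ground-truth table (see [simulateRnaSeq()]).
#' @slot termMap Synthetic term-to-gene map for enrichment tests.
#' @slot seed Integer seed used.
#' @slot config Generator configuration list.
#' @aliases SyntheticDataset-class
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  slots = c(annotation = "GenomeAnnotation", design = "data.frame",
            reads = "list", chip = "list", truth = "data.frame",
            termMap = "data.frameOrNULL", seed = "integer",
            config = "list"))

setValidity("SyntheticDataset", function(object) {
  if (nrow(object@design) &&
      !all(object@design$sample %in% names(object@reads)))
    return("every design row needs a matching read set")
  TRUE
})
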