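## Accessor generics and show methods. Slots are never reached into from
## user code; these accessors are the supported surface.

#' @describeIn GenomeAnnotation-class Gene features as a `GRanges`.
#' @param x,object An object of the documented class.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @describeIn GenomeAnnotation-class Named chromosome length vector.
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @describeIn GenomeAnnotation-class Gene identifiers.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("senseCounts", function(x) standardGeneric("senseCounts"))

#' @export
setGeneric("antisenseCounts", function(x) standardGeneric("antisenseCounts"))

#' @export
setGeneric("intergenicCounts", function(x) standardGeneric("intergenicCounts"))

#' @export
setGeneric("discardedCount", function(x) standardGeneric("discardedCount"))

#' @export
setGeneric("librarySize",
           function(x, which = c("assigned", "all")) standardGeneric("librarySize"))

#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @export
setGeneric("trackBinSize", function(x) standardGeneric("trackBinSize"))

#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))

#' @export
setGeneric("datasetAnnotation", function(x) standardGeneric("datasetAnnotation"))

#' @export
setGeneric("datasetDesign", function(x) standardGeneric("datasetDesign"))

#' @export
setGeneric("datasetReads", function(x, sample) standardGeneric("datasetReads"))

#' @export
setGeneric("datasetChip", function(x) standardGeneric("datasetChip"))

#' @export
setGeneric("datasetTruth", function(x) standardGeneric("datasetTruth"))

setMethod("genes", "GenomeAnnotation", function(x) x@genes)
setMethod("chromSizes", "GenomeAnnotation", function(x) x@chromSizes)
setMethod("geneIds", "GenomeAnnotation", function(x) mcols(x@genes)$gene_id)

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf("GenomeAnnotation: %d genes (%d protein-coding) on %d chromosomes\n",
              length(object@genes),
              sum(mcols(object@genes)$biotype == "protein_coding"),
              length(object@chromSizes)))
  cat(sprintf("  genome size: %s bp\n",
              format(sum(as.numeric(object@chromSizes)), big.mark = ",")))
})

#' @describeIn StrandedCounts-class Named vector of sense counts.
#' @export
setMethod("senseCounts", "StrandedCounts",
          function(x) setNames(x@sense, x@geneIds))

#' @describeIn StrandedCounts-class Named vector of antisense counts.
#' @export
setMethod("antisenseCounts", "StrandedCounts",
          function(x) setNames(x@antisense, x@geneIds))

#' @describeIn StrandedCounts-class Named vector of per-window intergenic
#'   counts.
#' @export
setMethod("intergenicCounts", "StrandedCounts",
          function(x) setNames(x@intergenic, x@intergenicIds))

#' @describeIn StrandedCounts-class Number of discarded ambiguous reads.
#' @export
setMethod("discardedCount", "StrandedCounts", function(x) x@discarded)

#' @describeIn StrandedCounts-class Library size: `"assigned"` (default)
#'   excludes discarded reads, `"all"` includes them.
#' @param which Library-size definition.
#' @export
setMethod("librarySize", "StrandedCounts", function(x, which = c("assigned", "all")) {
  which <- match.arg(which)
  n <- sum(x@sense) + sum(x@antisense) + sum(x@intergenic) +
    x@intergenicUnbinned
  if (which == "all") n + x@discarded else n
})

setMethod("show", "StrandedCounts", function(object) {
  cat(sprintf("StrandedCounts '%s': %d reads over %d genes\n",
              object@sample, object@nReads, length(object@geneIds)))
  cat(sprintf("  sense %d | antisense %d | intergenic %d | discarded %d\n",
              sum(object@sense), sum(object@antisense),
              sum(object@intergenic), object@discarded))
})

#' @describeIn ExpressionTable-class The long-format expression
#'   `data.frame`.
#' @export
setMethod("exprValues", "ExpressionTable", function(x) x@table)

#' @describeIn ExpressionTable-class Number of averaged replicates.
#' @export
setMethod("nReplicates", "ExpressionTable", function(x) x@nReplicates)

setMethod("show", "ExpressionTable", function(object) {
  cat(sprintf("ExpressionTable: %d feature x class rows, %d replicate(s) [%s]\n",
              nrow(object@table), object@nReplicates,
              paste(object@samples, collapse = ", ")))
})

#' @describeIn CoverageTrack-class Named list of per-chromosome vectors.
#' @export
setMethod("trackValues", "CoverageTrack", function(x) x@values)

#' @describeIn CoverageTrack-class Bin width in bp.
#' @export
setMethod("trackBinSize", "CoverageTrack", function(x) x@binSize)

#' @describeIn CoverageTrack-class Free-text label.
#' @export
setMethod("trackLabel", "CoverageTrack", function(x) x@label)

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack '%s': %d chromosome(s), bin %d bp\n",
              object@label, length(object@values), object@binSize))
})

#' Coerce a MetageneMatrix to a plain matrix
#'
#' @param x A [MetageneMatrix-class].
#' @param ... Ignored.
#' @return The underlying genes x bins numeric matrix.
#' @export
as.matrix.MetageneMatrix <- function(x, ...) x@values

setMethod("show", "MetageneMatrix", function(object) {
  cat(sprintf("MetageneMatrix (%s): %d genes x %d bins\n", object@anchor,
              nrow(object@values), ncol(object@values)))
})

#' @describeIn SyntheticDataset-class The [GenomeAnnotation-class].
#' @export
setMethod("datasetAnnotation", "SyntheticDataset", function(x) x@annotation)

#' @describeIn SyntheticDataset-class The sample design table.
#' @export
setMethod("datasetDesign", "SyntheticDataset", function(x) x@design)

#' @describeIn SyntheticDataset-class Stranded reads (`GRanges`) for one
#'   sample.
#' @param sample Sample name from the design table.
#' @export
setMethod("datasetReads", "SyntheticDataset", function(x, sample) {
  if (!sample %in% names(x@reads)) stop("unknown sample: ", sample)
  x@reads[[sample]]
})

#' @describeIn SyntheticDataset-class Named list of ChIP conditions.
#' @export
setMethod("datasetChip", "SyntheticDataset", function(x) x@chip)

#' @describeIn SyntheticDataset-class The planted ground-truth table.
#' @export
setMethod("datasetTruth", "SyntheticDataset", function(x) x@truth)

#' @describeIn SyntheticDataset-class The annotation.
#' @export
setMethod("genes", "SyntheticDataset", function(x) genes(x@annotation))

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset (seed %d): %d genes, %d samples, %d ChIP condition(s)\n",
              object@seed, length(genes(object@annotation)),
              nrow(object@design), length(object@chip)))
})
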