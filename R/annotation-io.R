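## Annotation reading/writing and stranded interval queries.
##
## Internal coordinates are GRanges-style (1-based, closed). GFF3 files
## are already in that convention; BED6 (0-based, half-open) is converted
## at the boundary by rtracklayer. Interval indexing is delegated to
## GenomicRanges::findOverlaps.

.validateAnnotationLines <- function(lines, format) {
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  ncol_min <- if (format == "gff3") 9L else 6L
  for (i in body) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (format == "bed6" && length(f) == 1L)
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < ncol_min)
      stop(sprintf("parse error at line %d: expected >= %d fields, found %d",
                   i, ncol_min, length(f)))
    pos <- if (format == "gff3") f[4:5] else f[2:3]
    if (anyNA(suppressWarnings(as.numeric(pos))))
      stop(sprintf("parse error at line %d: non-numeric coordinates", i))
  }
  invisible(TRUE)
}

.sequenceRegionSizes <- function(lines) {
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(sr)) return(NULL)
  parts <- strsplit(trimws(sr), "[ \t]+")
  setNames(vapply(parts, function(p) as.integer(p[4]), integer(1)),
           vapply(parts, function(p) p[2], character(1)))
}

#' Read a chromosome-sizes sidecar file
#'
#' Two-column TSV (`chrom`, `length`), the conventional `.chrom.sizes`
#' layout.
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  setNames(tab$length, tab$chrom)
}

#' Read a gene-level annotation (GFF3 or BED6)
#'
#' GFF3 records are filtered to `featureType` (default `"gene"`); gene ids
#' come from the `ID` attribute and biotypes from a `biotype` /
#' `gene_biotype` attribute when present (default `protein_coding`).
#' Chromosome sizes are taken, in order of precedence, from the
#' `chromSizes` argument (vector or path to a two-column TSV), from GFF3
#' `##sequence-region` directives, or — with a message — inferred from the
#' right-most feature end per chromosome.
#'
#' @param path Annotation file path.
#' @param format `"gff3"` or `"bed6"`.
#' @param chromSizes Named vector, path to a sizes TSV, or `NULL`.
#' @param featureType GFF3 `type` value(s) to keep.
#' @return A [GenomeAnnotation-class].
#' @export
readAnnotation <- function(path, format = c("gff3", "bed6"),
                           chromSizes = NULL, featureType = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  .validateAnnotationLines(lines, format)
  if (format == "gff3") {
    gr <- import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% featureType]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene records must carry an ID attribute")
    bt <- gr$biotype
    if (is.null(bt)) bt <- gr$gene_biotype
    if (is.null(bt)) bt <- rep("protein_coding", length(gr))
    feat <- granges(gr)
    mcols(feat)$gene_id <- ids
    mcols(feat)$biotype <- bt
    if (is.null(chromSizes)) chromSizes <- .sequenceRegionSizes(lines)
  } else {
    gr <- import(path, format = "bed")
    if (is.null(gr$name)) stop("BED6 annotation requires a name (gene_id) column")
    feat <- granges(gr)
    mcols(feat)$gene_id <- gr$name
    mcols(feat)$biotype <- rep("protein_coding", length(gr))
  }
  if (is.character(chromSizes) && length(chromSizes) == 1L)
    chromSizes <- readChromSizes(chromSizes)
  if (is.null(chromSizes)) {
    message("chromSizes not provided; inferring from feature extents")
    chromSizes <- vapply(split(end(feat), as.character(seqnames(feat))),
                         max, numeric(1))
  }
  names(feat) <- NULL
  GenomeAnnotation(feat, chromSizes)
}

#' Write a gene-level annotation
#'
#' GFF3 output carries `##sequence-region` directives and one `gene`
#' record per feature (`ID` and `biotype` attributes); BED6 output uses
#' the gene id as the name column and writes a `<path>.chrom.sizes`
#' sidecar. Output is byte-stable: no timestamps or tool banners.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param path Output path.
#' @param format `"gff3"` or `"bed6"`.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(annotation, path, format = c("gff3", "bed6")) {
  format <- match.arg(format)
  g <- genes(annotation)
  cs <- chromSizes(annotation)
  if (format == "gff3") {
    hdr <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(cs), cs))
    rows <- sprintf("%s\tantisenseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                    as.character(seqnames(g)), start(g), end(g),
                    as.character(strand(g)), mcols(g)$gene_id,
                    mcols(g)$biotype)
    writeLines(c(hdr, rows), path)
  } else {
    out <- granges(g)
    mcols(out)$name <- mcols(g)$gene_id
    mcols(out)$score <- 0L
    export(out, path, format = "bed")
    writeLines(sprintf("%s\t%d", names(cs), cs),
               paste0(path, ".chrom.sizes"))
  }
  invisible(path)
}

#' Query genes overlapping an interval
#'
#' Returns all features intersecting `[start, end]` (1-based, closed) on
#' the given chromosome, on either strand, ordered deterministically by
#' start then gene id. Equivalent to — and property-tested against — a
#' brute-force scan over all features.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param chrom Chromosome name.
#' @param start,end Query interval (1-based, closed, `start <= end`).
#' @return A `GRanges` of the overlapping gene features.
#' @export
queryOverlaps <- function(annotation, chrom, start, end) {
  cs <- chromSizes(annotation)
  if (!chrom %in% names(cs)) stop("unknown chromosome: ", chrom)
  if (start > end) stop("query start must be <= end")
  g <- genes(annotation)
  q <- GRanges(chrom, IRanges(start, end))
  GenomeInfoDb::seqlevels(q) <- GenomeInfoDb::seqlevels(g)
  hit <- g[subjectHits(findOverlaps(q, g, ignore.strand = TRUE))]
  hit[order(start(hit), mcols(hit)$gene_id)]
}

## TSS/CPS anchors derived from feature endpoints: TSS is the 5' end on
## the gene's strand, CPS the 3' end.
.tssPositions <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

.cpsPositions <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", end(genes), start(genes))
}

#' TSS and CPS anchor positions
#'
#' The transcription start site (TSS) is a feature's 5' endpoint on its
#' own strand; the cleavage-and-polyadenylation site (CPS) its 3'
#' endpoint. No UTR model is applied.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @return `data.frame` with `gene_id`, `chrom`, `strand`, `tss`, `cps`.
#' @export
geneAnchors <- function(annotation) {
  g <- genes(annotation)
  data.frame(gene_id = mcols(g)$gene_id,
             chrom = as.character(seqnames(g)),
             strand = as.character(strand(g)),
             tss = .tssPositions(g), cps = .cpsPositions(g),
             stringsAsFactors = FALSE)
}

#' Fixed-width intergenic windows
#'
#' Tiles the gaps between annotated loci (both strands collapsed) into
#' windows of at most `width` bp. Windows shorter than `minWidth` are
#' dropped. Window ids encode chromosome and start so the tiling is
#' reproducible from the annotation alone.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param width Window width in bp (default 500).
#' @param minWidth Minimum retained window width (default 50).
#' @return A `GRanges` with a `window_id` metadata column.
#' @export
intergenicWindows <- function(annotation, width = 500L, minWidth = 50L) {
  cs <- chromSizes(annotation)
  genome <- GRanges(names(cs), IRanges(1L, unname(cs)))
  GenomeInfoDb::seqlevels(genome) <- names(cs)
  occupied <- reduce(genes(annotation), ignore.strand = TRUE)
  gaps <- BiocGenerics::setdiff(genome, occupied, ignore.strand = TRUE)
  chromV <- character(); startV <- integer(); endV <- integer()
  for (i in seq_along(gaps)) {
    s <- start(gaps)[i]; e <- end(gaps)[i]
    st <- seq.int(s, e, by = width)
    chromV <- c(chromV, rep(as.character(seqnames(gaps))[i], length(st)))
    startV <- c(startV, st)
    endV <- c(endV, pmin(st + width - 1L, e))
  }
  win <- GRanges(chromV, IRanges(startV, endV))
  win <- win[width(win) >= minWidth]
  if (length(win))
    mcols(win)$window_id <- sprintf("ig_%s_%d",
                                    as.character(seqnames(win)), start(win))
  GenomeInfoDb::seqlevels(win) <- names(cs)
  seqlengths(win) <- cs
  win
}
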