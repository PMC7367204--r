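## On-disk layout for a SyntheticDataset (all plain text):
##   annotation.gff3, annotation.bed (+ .chrom.sizes)
##   reads/<sample>.bed                         one BED6 file per library
##   chip/<condition>.{ip,input}.bedGraph
##   design.tsv, truth.tsv, term_map.tsv, spike_counts.tsv
##   config.yaml, manifest.json (file list + md5 checksums + seed)

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read stranded read intervals from a BED6 file
#'
#' @param path BED6 file (0-based half-open on disk; converted to GRanges
#'   convention).
#' @param chromSizes Optional named lengths applied to the result.
#' @return A `GRanges` of stranded read intervals.
#' @export
readReads <- function(path, chromSizes = NULL) {
  gr <- import(path, format = "bed")
  gr <- granges(gr)
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    seqlengths(gr) <- chromSizes
  }
  gr
}

.writeReads <- function(reads, path) {
  out <- granges(reads)
  mcols(out)$name <- sprintf("read%d", seq_along(out))
  mcols(out)$score <- rep(0L, length(out))
  export(out, path, format = "bed")
  path
}

#' Write a SyntheticDataset to a directory
#'
#' Writes every component as plain text (see the layout above) and a
#' `manifest.json` listing all files with md5 checksums plus the seed.
#' Output is byte-deterministic for a fixed dataset.
#'
#' @param dataset A [SyntheticDataset-class].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly (list with `files`, `seed`).
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  if (length(dataset@chip))
    dir.create(file.path(dir, "chip"), showWarnings = FALSE)
  files <- character()
  add <- function(p) files <<- c(files, p)

  add(writeAnnotation(dataset@annotation, file.path(dir, "annotation.gff3"),
                      "gff3"))
  add(writeAnnotation(dataset@annotation, file.path(dir, "annotation.bed"),
                      "bed6"))
  add(file.path(dir, "annotation.bed.chrom.sizes"))
  for (smp in names(dataset@reads))
    add(.writeReads(dataset@reads[[smp]],
                    file.path(dir, "reads", paste0(smp, ".bed"))))
  spike <- NULL
  for (cond in names(dataset@chip)) {
    entry <- dataset@chip[[cond]]
    add(writeBedGraph(entry$ip,
                      file.path(dir, "chip", paste0(cond, ".ip.bedGraph"))))
    add(writeBedGraph(entry$input,
                      file.path(dir, "chip", paste0(cond, ".input.bedGraph"))))
    spike <- rbind(spike, data.frame(
      condition = cond, antibody = entry$antibody,
      ip_spike_reads = entry$ipSpikeReads,
      input_spike_reads = entry$inputSpikeReads,
      stringsAsFactors = FALSE))
  }
  if (!is.null(spike)) add(.writeTsv(spike, file.path(dir, "spike_counts.tsv")))
  add(.writeTsv(dataset@design, file.path(dir, "design.tsv")))
  add(.writeTsv(dataset@truth, file.path(dir, "truth.tsv")))
  if (!is.null(dataset@termMap))
    add(.writeTsv(dataset@termMap, file.path(dir, "term_map.tsv")))
  yaml::write_yaml(dataset@config, file.path(dir, "config.yaml"))
  add(file.path(dir, "config.yaml"))

  rel <- sub(paste0("^", dir, "/?"), "", files)
  manifest <- list(seed = dataset@seed,
                   files = lapply(seq_along(files), function(i)
                     list(path = rel[i],
                          md5 = unname(md5sum(files[i])))))
  write_json(manifest, file.path(dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a SyntheticDataset back from a directory
#'
#' Inverse of [writeDataset()]: rebuilds the in-memory object from the
#' plain-text layout. ChIP tracks are re-expanded to per-base vectors.
#'
#' @param dir Directory written by [writeDataset()].
#' @return A [SyntheticDataset-class].
#' @export
readDataset <- function(dir) {
  manifest <- read_json(file.path(dir, "manifest.json"))
  ann <- readAnnotation(file.path(dir, "annotation.gff3"), "gff3")
  design <- read.table(file.path(dir, "design.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
  truth <- read.table(file.path(dir, "truth.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  tmPath <- file.path(dir, "term_map.tsv")
  termMap <- if (file.exists(tmPath))
    read.table(tmPath, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else NULL
  reads <- lapply(design$sample, function(smp)
    readReads(file.path(dir, "reads", paste0(smp, ".bed")),
              chromSizes(ann)))
  names(reads) <- design$sample
  chip <- list()
  spikePath <- file.path(dir, "spike_counts.tsv")
  if (file.exists(spikePath)) {
    spike <- read.table(spikePath, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(spike))) {
      cond <- spike$condition[i]
      chip[[cond]] <- list(
        ip = readBedGraph(file.path(dir, "chip",
                                    paste0(cond, ".ip.bedGraph")),
                          chromSizes(ann), 1L,
                          sprintf("%s_%s_ip", spike$antibody[i], cond)),
        input = readBedGraph(file.path(dir, "chip",
                                       paste0(cond, ".input.bedGraph")),
                             chromSizes(ann), 1L,
                             sprintf("%s_input", cond)),
        ipSpikeReads = spike$ip_spike_reads[i],
        inputSpikeReads = spike$input_spike_reads[i],
        antibody = spike$antibody[i])
    }
  }
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  new("SyntheticDataset", annotation = ann, design = design,
      reads = reads, chip = chip, truth = truth, termMap = termMap,
      seed = as.integer(manifest$seed), config = config)
}
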