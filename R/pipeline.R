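## End-to-end orchestration: simulate -> quantify -> call -> compare ->
## ChIP/metagene -> report. Every intermediate is written as plain text
## and every reported number is recomputable from the archived
## intermediates; outputs are byte-deterministic for a fixed seed and
## configuration (timings go to the run log only).

#' Pipeline configuration
#'
#' @param rnaseq From [rnaSeqConfig()].
#' @param chip From [chipConfig()].
#' @param foldThreshold,rpkmFloor,pseudocount Differential-call rule
#'   parameters (see [callDifferential()]).
#' @param librarySize RPKM library-size definition (see
#'   [rpkmNormalize()]).
#' @param chipPseudocount Pseudocount for ChIP signal ratios.
#' @param cpsFlank CPS-anchored metagene flank (bp).
#' @param binSize Metagene bin width (bp).
#' @param scaledBodyBins,fromTss,beforeCps Gene-scaled metagene
#'   parameters (see [scaledMatrix()]).
#' @param troughFlankBins Half-window (bins) for [troughStatistic()].
#' @param clusterSize Genes per occupancy cluster (see [clusterGenes()]).
#' @return Configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(rnaseq = rnaSeqConfig(), chip = chipConfig(),
                           foldThreshold = 2, rpkmFloor = 1,
                           pseudocount = 0.1,
                           librarySize = "assigned",
                           chipPseudocount = 1,
                           cpsFlank = 1000L, binSize = 50L,
                           scaledBodyBins = 100L, fromTss = 200L,
                           beforeCps = 200L, troughFlankBins = 5L,
                           clusterSize = 500L) {
  list(rnaseq = rnaseq, chip = chip, foldThreshold = foldThreshold,
       rpkmFloor = rpkmFloor, pseudocount = pseudocount,
       librarySize = librarySize, chipPseudocount = chipPseudocount,
       cpsFlank = as.integer(cpsFlank), binSize = as.integer(binSize),
       scaledBodyBins = as.integer(scaledBodyBins),
       fromTss = as.integer(fromTss), beforeCps = as.integer(beforeCps),
       troughFlankBins = as.integer(troughFlankBins),
       clusterSize = as.integer(clusterSize))
}

#' Validate a pipeline configuration
#'
#' Returns diagnostics (empty when clean) instead of raising: threshold
#' ranges, design completeness, subset sizes, ChIP shape sanity and
#' metagene geometry are all checked.
#'
#' @param config From [pipelineConfig()].
#' @return Character vector of diagnostics.
#' @export
validateRunConfig <- function(config) {
  d <- character()
  chk <- function(cond, msg) if (cond) d <<- c(d, msg)
  chk(config$foldThreshold <= 1, "foldThreshold must be > 1")
  chk(config$rpkmFloor < 0, "rpkmFloor must be >= 0")
  chk(config$pseudocount <= 0, "pseudocount must be positive")
  rc <- config$rnaseq
  chk(rc$depth <= 0, "rnaseq: library depth must be positive")
  chk(rc$replicates < 1,
      "rnaseq: every strain x treatment cell needs >= 1 replicate")
  chk(sum(rc$subsetSizes) > rc$nGenes,
      "rnaseq: planted subset sizes exceed the number of genes")
  cc <- config$chip
  chk(length(cc$conditions) == 0, "chip: no conditions configured")
  for (nm in names(cc$conditions)) {
    td <- cc$conditions[[nm]]$troughDepth
    chk(!is.null(td) && (td < 0 || td > 1),
        sprintf("chip condition '%s': troughDepth outside [0, 1]", nm))
  }
  chk(config$cpsFlank %% config$binSize != 0,
      "cpsFlank must be a multiple of binSize")
  chk(config$troughFlankBins * config$binSize > config$cpsFlank,
      "trough window exceeds the CPS-anchored flank")
  d
}

.log <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

.avgKey <- function(strain, treatment) paste(strain, treatment, sep = "_")

## Per-gene antisense fold induction (mutant vs wild type, same
## treatment), from a calls table.
.foldInduction <- function(calls, ids, pseudocount) {
  anti <- calls[calls$class == "antisense", ]
  anti <- anti[match(ids, anti$feature_id), ]
  (anti$mut_rpkm + pseudocount) / (anti$wt_rpkm + pseudocount)
}

#' Run the full pipeline
#'
#' Executes simulate, quantify, differential-call, comparison (overlap /
#' synergy / enrichment), ChIP + metagene and truth-evaluation stages in
#' order, writing all intermediates plus `report.json` and `report.md`
#' into `outDir`. Identical configuration and seed give byte-identical
#' outputs (the timing log `pipeline.log` aside).
#'
#' @param config From [pipelineConfig()].
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed.
#' @param writeReadFiles Also write per-sample BED read files (off by
#'   default; they dominate disk usage).
#' @return The report, invisibly (a nested list mirroring
#'   `report.json`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, seed = 1L,
                        writeReadFiles = FALSE) {
  diags <- validateRunConfig(config)
  if (length(diags))
    stop("invalid configuration:\n  ", paste(diags, collapse = "\n  "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logCon <- file(file.path(outDir, "pipeline.log"), open = "wt")
  on.exit(close(logCon))
  t0 <- Sys.time()
  stage <- function(nm) .log(logCon, "[%s] %+.1fs", nm,
                             as.numeric(Sys.time() - t0, units = "secs"))

  stage("simulate")
  ds <- simulateDataset(config$rnaseq, config$chip, seed)
  ann <- datasetAnnotation(ds)
  design <- datasetDesign(ds)
  truth <- datasetTruth(ds)
  pc <- geneIds(ann)[mcols(genes(ann))$biotype == "protein_coding"]
  if (writeReadFiles) writeDataset(ds, file.path(outDir, "dataset"))

  stage("quantify")
  windows <- intergenicWindows(ann)
  tables <- list()
  countRows <- list()
  for (i in seq_len(nrow(design))) {
    smp <- design$sample[i]
    cnt <- countReads(datasetReads(ds, smp), ann, sample = smp,
                      windows = windows)
    tables[[smp]] <- rpkmNormalize(cnt, ann, config$librarySize)
    countRows[[smp]] <- data.frame(
      sample = smp, gene_id = geneIds(ann),
      sense = unname(senseCounts(cnt)),
      antisense = unname(antisenseCounts(cnt)),
      stringsAsFactors = FALSE)
  }
  .writeTsv(do.call(rbind, countRows), file.path(outDir, "counts.tsv"))
  avg <- list()
  for (st in unique(design$strain)) for (tr in unique(design$treatment)) {
    smps <- design$sample[design$strain == st & design$treatment == tr]
    avg[[.avgKey(st, tr)]] <- averageReplicates(tables[smps])
  }
  rpkmOut <- do.call(rbind, lapply(names(avg), function(k) {
    tab <- exprValues(avg[[k]])
    cbind(condition = k, tab)
  }))
  .writeTsv(rpkmOut, file.path(outDir, "rpkm.tsv"))

  stage("diffcall")
  mutants <- setdiff(unique(design$strain), "WT")
  calls <- list()
  fractions <- list()
  for (st in mutants) for (tr in unique(design$treatment)) {
    key <- .avgKey(st, tr)
    calls[[key]] <- callDifferential(avg[[key]], avg[[.avgKey("WT", tr)]],
                                     config$foldThreshold,
                                     config$rpkmFloor, config$pseudocount)
    fr <- categoryFractions(calls[[key]], length(pc))
    fractions[[key]] <- cbind(comparison = key, fr)
  }
  callsOut <- do.call(rbind, lapply(names(calls), function(k)
    cbind(comparison = k, calls[[k]])))
  .writeTsv(callsOut, file.path(outDir, "calls.tsv"))
  .writeTsv(do.call(rbind, fractions), file.path(outDir, "fractions.tsv"))

  stage("compare")
  drug <- "3MBPP1"
  upSets <- lapply(mutants, function(st)
    differentialSet(calls[[.avgKey(st, drug)]]))
  names(upSets) <- mutants
  pairs <- utils::combn(mutants, 2, simplify = FALSE)
  overlaps <- lapply(pairs, function(p)
    c(list(set_A = p[1], set_B = p[2]),
      hypergeometricOverlap(upSets[[p[1]]], upSets[[p[2]]], pc)))
  shared <- sort(Reduce(intersect,
                        upSets[c("cdk9as", "htb1K119R")]))
  tripleInt <- length(Reduce(intersect, upSets))
  synergy <- NULL
  if (length(shared)) {
    foldDouble <- .foldInduction(calls[[.avgKey("cdk9as_htb1K119R", drug)]],
                                 shared, config$pseudocount)
    synergy <- list(
      n_shared = length(shared),
      vs_cdk9as = synergyTest(
        foldDouble, .foldInduction(calls[[.avgKey("cdk9as", drug)]],
                                   shared, config$pseudocount)),
      vs_htb1K119R = synergyTest(
        foldDouble, .foldInduction(calls[[.avgKey("htb1K119R", drug)]],
                                   shared, config$pseudocount)))
  }
  overlapReport <- list(universe = length(pc),
                        antisense_up_sizes = lapply(upSets, length),
                        pairwise = overlaps,
                        shared_cdk9as_htb1K119R = length(shared),
                        triple_intersection = tripleInt,
                        synergy = synergy)
  write_json(overlapReport, file.path(outDir, "overlap.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)

  stage("enrichment")
  enrich <- NULL
  if (!is.null(ds@termMap) && length(upSets[["cdk9as"]])) {
    enrich <- termEnrichment(upSets[["cdk9as"]], ds@termMap, pc)
    .writeTsv(enrich, file.path(outDir, "enrichment.tsv"))
  }

  stage("chip")
  chipReport <- list()
  profilesOut <- list()
  normTracks <- list()
  anchorBin <- config$cpsFlank %/% config$binSize + 1L
  for (cond in names(datasetChip(ds))) {
    entry <- datasetChip(ds)[[cond]]
    norm <- normalizedSignal(entry$ip, entry$input, entry$ipSpikeReads,
                             entry$inputSpikeReads,
                             config$chipPseudocount)
    normTracks[[cond]] <- norm
    cpsProf <- metaProfile(anchoredMatrix(norm, ann, "CPS",
                                          config$cpsFlank, config$cpsFlank,
                                          config$binSize), "mean")
    scaledProf <- metaProfile(
      scaledMatrix(norm, ann, config$scaledBodyBins, config$fromTss,
                   config$beforeCps, binSize = config$binSize), "mean")
    trough <- troughStatistic(cpsProf, anchorBin, config$troughFlankBins)
    occ <- geneOccupancy(norm, ann)
    clusters <- clusterGenes(occ, "fixed_size", config$clusterSize)
    .writeTsv(clusters, file.path(outDir, sprintf("clusters_%s.tsv", cond)))
    clusterMeans <- tapply(clusters$score, clusters$cluster, mean)
    chipReport[[cond]] <- list(
      spike_scale = spikeScale(entry$ipSpikeReads, entry$inputSpikeReads),
      trough_statistic = trough,
      n_clusters = length(clusterMeans),
      cluster_mean_occupancy = as.numeric(clusterMeans))
    profilesOut[[paste0(cond, "_cps")]] <- cpsProf
    profilesOut[[paste0(cond, "_scaled")]] <- scaledProf
  }
  if (length(normTracks) >= 2) {
    nm <- names(normTracks)[1:2]
    lr <- ratioTrack(normTracks[[nm[1]]], normTracks[[nm[2]]], "log2",
                     config$chipPseudocount)
    profilesOut[[sprintf("log2_%s_vs_%s_cps", nm[1], nm[2])]] <-
      metaProfile(anchoredMatrix(lr, ann, "CPS", config$cpsFlank,
                                 config$cpsFlank, config$binSize), "mean")
  }
  profDf <- do.call(rbind, lapply(names(profilesOut), function(nm)
    data.frame(profile = nm, bin = seq_along(profilesOut[[nm]]),
               value = profilesOut[[nm]], stringsAsFactors = FALSE)))
  .writeTsv(profDf, file.path(outDir, "metagene_profiles.tsv"))

  stage("truth")
  confusion <- list()
  for (st in mutants) {
    key <- .avgKey(st, drug)
    planted <- truth$gene_id[truth[[sprintf("fold_%s_%s", st, drug)]] > 1]
    called <- upSets[[st]]
    tp <- length(intersect(called, planted))
    fp <- length(setdiff(called, planted))
    fn <- length(setdiff(planted, called))
    tn <- length(pc) - tp - fp - fn
    confusion[[key]] <- list(
      planted = length(planted), called = length(called),
      TP = tp, FP = fp, FN = fn, TN = tn,
      sensitivity = if (length(planted)) tp / length(planted) else NA,
      fdr = if (length(called)) fp / length(called) else 0,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA)
  }

  stage("report")
  cfgYaml <- as.yaml(config)
  cfgPath <- file.path(outDir, "run_config.yaml")
  writeLines(cfgYaml, cfgPath)
  report <- list(
    provenance = list(package = "antisenseq",
                      version = as.character(packageVersion("antisenseq")),
                      seed = seed, config_md5 = unname(md5sum(cfgPath))),
    design = list(n_genes = length(geneIds(ann)),
                  n_protein_coding = length(pc),
                  n_samples = nrow(design)),
    category_fractions = lapply(fractions, function(fr)
      setNames(as.list(fr$percent),
               paste(fr$class, fr$direction, sep = "_"))),
    overlap = overlapReport,
    enrichment_top = if (!is.null(enrich))
      head(enrich[, c("term", "odds_ratio", "p_value", "p_adjusted")], 5)
      else NULL,
    chip = chipReport,
    truth_evaluation = confusion)
  write_json(report, file.path(outDir, "report.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeReportMd(report, file.path(outDir, "report.md"))
  stage("done")
  invisible(report)
}

.writeReportMd <- function(report, path) {
  num <- function(x) formatC(x, digits = 4, format = "g")
  lines <- c(
    "# antisenseq run report", "",
    sprintf("- package version: %s, seed: %d",
            report$provenance$version, report$provenance$seed),
    sprintf("- genes: %d (%d protein-coding), samples: %d",
            report$design$n_genes, report$design$n_protein_coding,
            report$design$n_samples), "",
    "## Antisense up-calls (drug-treated, vs wild type)", "")
  for (nm in names(report$overlap$antisense_up_sizes))
    lines <- c(lines, sprintf("- %s: %d genes (%.1f%% of protein-coding)",
                              nm, report$overlap$antisense_up_sizes[[nm]],
                              100 * report$overlap$antisense_up_sizes[[nm]] /
                                report$overlap$universe))
  lines <- c(lines, "",
             sprintf("- shared (kinase & histone single mutants): %d genes",
                     report$overlap$shared_cdk9as_htb1K119R))
  for (ov in report$overlap$pairwise)
    lines <- c(lines, sprintf(
      "- overlap %s vs %s: %d genes, hypergeometric log10(p) = %s",
      ov$set_A, ov$set_B, ov$n_intersection, num(ov$log10_p)))
  syn <- report$overlap$synergy
  if (!is.null(syn))
    lines <- c(lines, "", "## Synergy over the shared antisense set", "",
               sprintf("- median fold induction: double %s vs single %s / %s",
                       num(syn$vs_cdk9as$median_double),
                       num(syn$vs_cdk9as$median_single),
                       num(syn$vs_htb1K119R$median_single)),
               sprintf("- Mann-Whitney p (double vs kinase single): %s",
                       num(syn$vs_cdk9as$p_value)))
  lines <- c(lines, "", "## ChIP trough statistics", "")
  for (nm in names(report$chip))
    lines <- c(lines, sprintf("- %s: trough = %s (spike scale %s)", nm,
                              num(report$chip[[nm]]$trough_statistic),
                              num(report$chip[[nm]]$spike_scale)))
  lines <- c(lines, "", "## Truth recovery", "")
  for (nm in names(report$truth_evaluation)) {
    tv <- report$truth_evaluation[[nm]]
    lines <- c(lines, sprintf(
      "- %s: sensitivity %s, FDR %s (TP %d, FP %d, FN %d)", nm,
      num(tv$sensitivity), num(tv$fdr), tv$TP, tv$FP, tv$FN))
  }
  writeLines(lines, path)
}
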