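# Generator contracts: determinism, noise-model correctness, planted
# structure, configuration errors, ChIP closed forms, and file round
# trips.

test_that("identical seed and configuration give identical datasets", {
  cfg <- rnaSeqConfig(nGenes = 50L, depth = 5000,
                      subsetSizes = c(cdk9_only = 3L, h2bub1_only = 3L,
                                      shared = 2L, double_only = 4L))
  a <- simulateRnaSeq(cfg, seed = 9)
  b <- simulateRnaSeq(cfg, seed = 9)
  expect_identical(datasetTruth(a), datasetTruth(b))
  for (smp in datasetDesign(a)$sample)
    expect_identical(as.data.frame(datasetReads(a, smp)),
                     as.data.frame(datasetReads(b, smp)))
  c1 <- simulateChip(datasetAnnotation(a), chipConfig(), seed = 9)
  c2 <- simulateChip(datasetAnnotation(a), chipConfig(), seed = 9)
  expect_identical(trackValues(c1$control$ip), trackValues(c2$control$ip))
  expect_identical(c1$control$ipSpikeReads, c2$control$ipSpikeReads)
})

test_that("planted subsets are disjoint and sized as configured", {
  cfg <- smallRnaConfig()
  truth <- datasetTruth(simulateRnaSeq(cfg, seed = 4))
  tab <- table(truth$subset)
  for (nm in names(cfg$subsetSizes))
    expect_equal(unname(tab[nm]), unname(cfg$subsetSizes[nm]))
  # fold pattern consistent with subset labels
  expect_true(all(truth$fold_WT_DMSO == 1))
  expect_true(all(truth$fold_cdk9as_DMSO == 1))
  sh <- truth$subset == "shared"
  expect_true(all(truth$fold_cdk9as_3MBPP1[sh] == cfg$singleFold))
  expect_true(all(truth$fold_htb1K119R_DMSO[sh] == cfg$singleFold))
  expect_true(all(truth$fold_cdk9as_htb1K119R_3MBPP1[sh] ==
                    cfg$singleFold * cfg$synergyFactor))
  expect_true(all(truth$fold_cdk9as_htb1K119R_3MBPP1[
    truth$subset == "double_only"] == cfg$doubleOnlyFold))
})

test_that("all reads fall within chromosome bounds", {
  ds <- simulateRnaSeq(smallRnaConfig(), seed = 12)
  cs <- chromSizes(datasetAnnotation(ds))
  for (smp in head(datasetDesign(ds)$sample, 4)) {
    rd <- datasetReads(ds, smp)
    expect_true(all(start(rd) >= 1))
    expect_true(all(end(rd) <= cs[as.character(seqnames(rd))]))
  }
})

test_that("empirical counts follow the configured Poisson expectations", {
  # 200 independent generations of a tiny design; per-gene sense counts
  # are compared to each generation's own truth-table expectation via
  # pooled standardized residuals z = (obs - mu) / sqrt(mu), which are
  # mean 0, variance 1 under a correct Poisson noise model
  cfg <- rnaSeqConfig(nGenes = 12L, depth = 3000, replicates = 1L,
                      nonCodingFraction = 0,
                      subsetSizes = c(cdk9_only = 1L, h2bub1_only = 1L,
                                      shared = 1L, double_only = 1L))
  nGen <- 200L
  z <- numeric(0)
  for (k in seq_len(nGen)) {
    ds <- simulateRnaSeq(cfg, seed = 5000 + k)
    ann <- datasetAnnotation(ds)
    truth <- datasetTruth(ds)
    mu <- truth$baseline_sense_rpkm * width(genes(ann)) * cfg$depth / 1e9
    obs <- unname(senseCounts(countReads(datasetReads(ds, "WT_DMSO_rep1"),
                                         ann, "wt")))
    z <- c(z, (obs - mu) / sqrt(mu))
  }
  # mean within 3 standard errors of 0; variance close to 1
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(var(z) - 1), 0.15)
})

test_that("zero-noise null dataset yields no antisense_up calls", {
  cfg <- rnaSeqConfig(nGenes = 100L, depth = 3e4, noise = "none",
                      subsetSizes = c(cdk9_only = 0L, h2bub1_only = 0L,
                                      shared = 0L, double_only = 0L))
  ds <- simulateRnaSeq(cfg, seed = 3)
  avg <- quantifyConditions(ds, c("WT_3MBPP1", "cdk9as_3MBPP1"))
  calls <- callDifferential(avg$cdk9as_3MBPP1, avg$WT_3MBPP1)
  expect_length(differentialSet(calls), 0)
  expect_length(differentialSet(calls, "sense", "up"), 0)
})

test_that("invalid generator configurations are rejected", {
  expect_error(rnaSeqConfig(nGenes = 10L,
                            subsetSizes = c(cdk9_only = 5L, h2bub1_only = 5L,
                                            shared = 5L, double_only = 5L)),
               "exceed")
  expect_error(rnaSeqConfig(depth = 0), "depth")
  expect_error(rnaSeqConfig(singleFold = -1), "non-negative")
  expect_error(chipConfig(plateauScale = -1), "negative")
  expect_error(chipConfig(troughDepth = 1.5), "troughDepth")
})

test_that("ChIP tracks realize the configured trough depth in closed form", {
  set.seed(1)
  ann <- randomAnnotation(1)  # irrelevant; use generator annotation below
  ds <- simulateRnaSeq(tinyRnaConfig(60L, 1000), seed = 21)
  ann <- datasetAnnotation(ds)
  cfg <- chipConfig(conditions = list(
    deep = list(troughDepth = 0.6), flat = list(troughDepth = 0)))
  chip <- simulateChip(ann, cfg, seed = 21)
  anchors <- geneAnchors(ann)
  for (cond in c("deep", "flat")) {
    e <- chip[[cond]]
    ipv <- trackValues(e$ip)
    depth <- e$shape$troughDepth
    # at the CPS the gene contribution is (1 - depth) * plateau, on top
    # of the background; 300 bp upstream it is the full plateau
    for (i in seq_len(10)) {
      h <- cfg$plateauScale * e$exprScores[i]
      dir <- if (anchors$strand[i] == "+") 1L else -1L
      atCps <- ipv[[anchors$chrom[i]]][anchors$cps[i]]
      atBody <- ipv[[anchors$chrom[i]]][anchors$cps[i] - dir * 300L]
      expect_equal(atCps, cfg$background + (1 - depth) * h,
                   tolerance = 0.02)
      expect_equal(atBody, cfg$background + h, tolerance = 0.02)
    }
  }
})

test_that("equal spike fractions cancel sequencing depth differences", {
  ds <- simulateRnaSeq(tinyRnaConfig(40L, 1000), seed = 2)
  ann <- datasetAnnotation(ds)
  cfg <- chipConfig(conditions = list(
    shallow = list(depthFactor = 1), deep = list(depthFactor = 2)))
  chip <- simulateChip(ann, cfg, seed = 2)
  n1 <- normalizedSignal(chip$shallow$ip, chip$shallow$input,
                         chip$shallow$ipSpikeReads,
                         chip$shallow$inputSpikeReads, pseudocount = 1e-9)
  n2 <- normalizedSignal(chip$deep$ip, chip$deep$input,
                         chip$deep$ipSpikeReads,
                         chip$deep$inputSpikeReads, pseudocount = 1e-9)
  expect_equal(trackValues(n1), trackValues(n2), tolerance = 1e-3)
})

test_that("datasets round-trip through the on-disk layout", {
  ds <- simulateDataset(tinyRnaConfig(30L, 2000), chipConfig(), seed = 6)
  dir <- file.path(tempdir(), "ds-roundtrip")
  manifest <- writeDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(all(vapply(manifest$files, function(f)
    nzchar(f$md5), logical(1))))
  back <- readDataset(dir)
  expect_equal(start(genes(back)), start(genes(ds)))
  expect_equal(geneIds(datasetAnnotation(back)),
               geneIds(datasetAnnotation(ds)))
  expect_equal(datasetTruth(back)$subset, datasetTruth(ds)$subset)
  smp <- datasetDesign(ds)$sample[1]
  expect_equal(as.data.frame(granges(datasetReads(back, smp))),
               as.data.frame(granges(datasetReads(ds, smp))))
  expect_equal(datasetChip(back)$control$ipSpikeReads,
               datasetChip(ds)$control$ipSpikeReads)
  expect_equal(trackValues(datasetChip(back)$control$ip)$chrI,
               trackValues(datasetChip(ds)$control$ip)$chrI,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("an empty read set still writes a valid BED file", {
  ds <- simulateRnaSeq(tinyRnaConfig(20L, 1000), seed = 1)
  path <- tempfile(fileext = ".bed")
  antisenseq:::.writeReads(GRanges(), path)
  expect_true(file.exists(path))
  expect_length(readReads(path), 0)
})
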