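# Metagene construction: orientation, brute-force window equivalence,
# scaling laws, clustering determinism, and the trough statistic.

twoGeneAnnotation <- function() {
  gr <- GRanges("chrI", IRanges(c(2001, 6001), c(3000, 7000)),
                strand = c("+", "-"), gene_id = c("gPlus", "gMinus"),
                biotype = "protein_coding")
  GenomeAnnotation(gr, c(chrI = 10000))
}

test_that("a constant track gives constant matrices and profiles", {
  ann <- twoGeneAnnotation()
  tr <- constantTrack(3.5, chromSizes(ann))
  m <- anchoredMatrix(tr, ann, "TSS", 500, 500, 50)
  expect_true(all(as.matrix(m) == 3.5))
  sm <- scaledMatrix(tr, ann, 50, 100, 100)
  expect_true(all(as.matrix(sm) == 3.5))
  expect_equal(metaProfile(m, "mean"), rep(3.5, 20))
})

test_that("minus-strand rows are oriented 5' to 3'", {
  ann <- twoGeneAnnotation()
  # step up 100 bp downstream of each TSS: for gMinus (TSS at 7000) the
  # high region is genomic [5000, 6900]
  v <- rep(1, 10000)
  v[2101:4000] <- 9      # gPlus: TSS 2001, step at +100
  v[5000:6900] <- 9      # gMinus: TSS 7000, step at +100 (leftward)
  tr <- CoverageTrack(list(chrI = v))
  m <- as.matrix(anchoredMatrix(tr, ann, "TSS", 200, 400, 50))
  # both rows must show the same oriented step at +100
  expect_equal(m["gPlus", ], m["gMinus", ])
  expect_true(all(m["gPlus", 1:6] == 1))   # upstream + first 100 bp
  expect_true(all(m["gPlus", 7:12] == 9))  # beyond +100
})

test_that("mirroring track and strand leaves metagene rows unchanged", {
  set.seed(21)
  len <- 10000L
  v <- runif(len)
  gr1 <- GRanges("chrI", IRanges(4001, 5000), strand = "+",
                 gene_id = "g", biotype = "protein_coding")
  ann1 <- GenomeAnnotation(gr1, c(chrI = len))
  # mirror: position p -> len + 1 - p; the + gene becomes a - gene
  gr2 <- GRanges("chrI", IRanges(len + 1 - 5000, len + 1 - 4001),
                 strand = "-", gene_id = "g", biotype = "protein_coding")
  ann2 <- GenomeAnnotation(gr2, c(chrI = len))
  t1 <- CoverageTrack(list(chrI = v))
  t2 <- CoverageTrack(list(chrI = rev(v)))
  for (anchor in c("TSS", "CPS")) {
    m1 <- as.matrix(anchoredMatrix(t1, ann1, anchor, 300, 300, 50))
    m2 <- as.matrix(anchoredMatrix(t2, ann2, anchor, 300, 300, 50))
    expect_equal(m1, m2)
  }
  s1 <- as.matrix(scaledMatrix(t1, ann1, 40, 100, 100))
  s2 <- as.matrix(scaledMatrix(t2, ann2, 40, 100, 100))
  expect_equal(s1, s2)
})

test_that("anchored rows equal brute-force per-base window means", {
  set.seed(22)
  ann <- randomAnnotation(40, chromLen = 30000L)
  tr <- CoverageTrack(list(chr1 = runif(30000), chr2 = runif(30000)))
  up <- 400L; dn <- 600L; bs <- 50L
  m <- suppressMessages(anchoredMatrix(tr, ann, "TSS", up, dn, bs))
  anchors <- geneAnchors(ann)
  vals <- as.matrix(m)
  for (gid in rownames(vals)) {
    a <- anchors[anchors$gene_id == gid, ]
    dir <- if (a$strand == "+") 1 else -1
    offsets <- seq.int(-up, dn - 1L)
    perBase <- trackValues(tr)[[a$chrom]][a$tss + dir * offsets]
    oracle <- colMeans(matrix(perBase, nrow = bs))
    expect_equal(unname(vals[gid, ]), oracle, tolerance = 1e-9)
  }
})

test_that("a linear ramp scales into linear bin means for any length", {
  # two genes of different length carrying the same relative shape
  gr <- GRanges("chrI", IRanges(c(1001, 10001), c(2000, 12000)),
                strand = "+", gene_id = c("gShort", "gLong"),
                biotype = "protein_coding")
  ann <- GenomeAnnotation(gr, c(chrI = 20000))
  v <- rep(0, 20000)
  v[1001:2000] <- seq(0, 1, length.out = 1000)
  v[10001:12000] <- seq(0, 1, length.out = 2000)
  tr <- CoverageTrack(list(chrI = v))
  sm <- as.matrix(scaledMatrix(tr, ann, nBodyBins = 20, fromTss = 0,
                               beforeCps = 0))
  # rows agree within binning error despite the 2x length difference
  expect_equal(sm["gShort", ], sm["gLong", ], tolerance = 0.01)
  # bin means of a linear ramp are themselves linear
  d <- diff(sm["gLong", ])
  expect_equal(d, rep(d[1], 19), tolerance = 1e-6)
})

test_that("genes too short or out of bounds are dropped with a message", {
  gr <- GRanges("chrI", IRanges(c(101, 5001), c(150, 7000)),
                strand = "+", gene_id = c("tiny", "ok"),
                biotype = "protein_coding")
  ann <- GenomeAnnotation(gr, c(chrI = 10000))
  tr <- constantTrack(1, chromSizes(ann))
  # the 50-bp gene cannot fill 100 body bins
  expect_message(m <- scaledMatrix(tr, ann, 100, 0, 0), "dropped")
  expect_equal(rownames(as.matrix(m)), "ok")
  expect_message(a <- anchoredMatrix(tr, ann, "TSS", 500, 500, 50),
                 "dropped")
  expect_equal(rownames(as.matrix(a)), "ok")
  expect_error(anchoredMatrix(tr, ann, "TSS", 500, 500, 50,
                              geneIds = "absent"), "empty")
})

test_that("profiles apply column statistics with NA masking", {
  m <- suppressMessages(anchoredMatrix(
    constantTrack(2, c(chrI = 10000)),
    GenomeAnnotation(GRanges("chrI", IRanges(3001, 4000), strand = "+",
                             gene_id = "g", biotype = "protein_coding"),
                     c(chrI = 10000)), "TSS", 500, 500, 50))
  expect_equal(metaProfile(m, "mean"), unname(as.matrix(m)[1, ]))
  set.seed(30)
  vals <- matrix(runif(60), 6, 10)
  mm <- new("MetageneMatrix",
            values = `rownames<-`(vals, sprintf("g%d", 1:6)),
            anchor = "TSS", upstream = 0L, downstream = 0L,
            binSize = 50L, nBodyBins = 0L)
  expect_equal(metaProfile(mm, "median"), apply(vals, 2, median))
})

test_that("clustering is a deterministic ordered partition", {
  set.seed(23)
  scores <- setNames(runif(1500), sprintf("g%04d", 1:1500))
  cl <- clusterGenes(scores, "fixed_size", 500)
  expect_equal(as.vector(table(cl$cluster)), rep(500L, 3))
  expect_setequal(cl$gene_id, names(scores))
  means <- tapply(cl$score, cl$cluster, mean)
  expect_true(all(diff(means) < 0))  # ordered high to low
  # all-equal scores fall back to lexicographic gene order
  eq <- clusterGenes(setNames(rep(1, 5), c("e", "b", "a", "d", "c")),
                     "fixed_size", 2)
  expect_equal(eq$gene_id, c("a", "b", "c", "d", "e"))
  # quantile mode: sizes differ by at most one
  q <- clusterGenes(setNames(runif(103), sprintf("q%03d", 1:103)),
                    "quantile", 4)
  expect_lte(diff(range(table(q$cluster))), 1)
  expect_error(clusterGenes(setNames(NaN, "x"), "fixed_size", 1), "finite")
})

test_that("the trough statistic reads depth off a profile", {
  expect_equal(troughStatistic(rep(2, 21), 11, 5), 1)
  prof <- rep(10, 21); prof[9:13] <- c(8, 5, 4, 5, 8)
  expect_equal(troughStatistic(prof, 11, 5), 0.4)
  expect_error(troughStatistic(prof, 2, 5), "bounds")
  expect_error(troughStatistic(rep(0, 21), 11, 5), "shoulder")
})
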