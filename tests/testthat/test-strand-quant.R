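# Read classification, counting and RPKM: worked micro-cases, the
# brute-force equivalence property, conservation, and formula oracles.

miniAnnotation <- function() {
  # two tandem + genes, one - gene overlapping the first, one nc gene
  gr <- GRanges("chrI",
                IRanges(c(1001, 2001, 1101, 5001),
                        c(1500, 2500, 1300, 5400)),
                strand = c("+", "+", "-", "+"),
                gene_id = c("gA", "gB", "gC", "gN"),
                biotype = c("protein_coding", "protein_coding",
                            "protein_coding", "non_coding"))
  GenomeAnnotation(gr, c(chrI = 10000))
}

test_that("classifier applies the sense/antisense/discard rules", {
  ann <- miniAnnotation()
  reads <- GRanges("chrI",
                   IRanges(c(1350, 1901, 1420, 3001, 1150),
                           width = 50),
                   strand = c("+", "-", "-", "+", "-"))
  asg <- assignReads(reads, ann)
  # read 1: + inside gA -> sense
  expect_equal(asg$category[1], "sense")
  expect_equal(asg$gene_id[1], "gA")
  # read 2: - read spanning the gap but only gB under it? 1901-1950
  # overlaps no gene -> intergenic
  expect_equal(asg$category[2], "intergenic")
  # read 3: - read inside gA only -> antisense to gA
  expect_equal(asg$category[3], "antisense")
  expect_equal(asg$gene_id[3], "gA")
  # read 4: no overlap -> intergenic
  expect_equal(asg$category[4], "intergenic")
  # read 5: - read over gA(+) and gC(-): same-strand gC wins -> sense
  expect_equal(asg$category[5], "sense")
  expect_equal(asg$gene_id[5], "gC")
})

test_that("a read antisense to more than one gene is discarded", {
  gr <- GRanges("chrI", IRanges(c(1001, 1501), c(1490, 2000)),
                strand = "+", gene_id = c("gA", "gB"),
                biotype = "protein_coding")
  ann <- GenomeAnnotation(gr, c(chrI = 4000))
  spanning <- GRanges("chrI", IRanges(1470, width = 50), strand = "-")
  expect_equal(assignReads(spanning, ann)$category, "discarded")
  single <- GRanges("chrI", IRanges(1100, width = 50), strand = "-")
  expect_equal(assignReads(single, ann)$category, "antisense")
})

test_that("sense ties break to the lexicographically smallest gene id", {
  gr <- GRanges("chrI", IRanges(c(1001, 1001), c(1500, 1500)),
                strand = "+", gene_id = c("gB", "gA"),
                biotype = "protein_coding")
  ann <- GenomeAnnotation(gr, c(chrI = 4000))
  r <- GRanges("chrI", IRanges(1200, width = 50), strand = "+")
  expect_equal(assignReads(r, ann)$gene_id, "gA")
})

test_that("the dUTP convention flag flips the effective strand", {
  ann <- miniAnnotation()
  r <- GRanges("chrI", IRanges(2100, width = 50), strand = "-")
  expect_equal(assignReads(r, ann)$category, "antisense")
  flipped <- assignReads(r, ann, convention = "read_is_opposite")
  expect_equal(flipped$category, "sense")
  expect_equal(flipped$gene_id, "gB")
})

test_that("classifier equals brute-force enumeration on random data", {
  for (seed in 1:3) {
    set.seed(100 + seed)
    ann <- randomAnnotation(100)
    reads <- randomReads(2000, ann)
    fast <- assignReads(reads, ann)
    slow <- bruteClassify(reads, ann)
    expect_identical(fast$category, slow$category)
    expect_identical(fast$gene_id, slow$gene_id)
  }
})

test_that("read conservation holds exactly and counts match assignments", {
  set.seed(42)
  ann <- randomAnnotation(80)
  reads <- randomReads(5000, ann)
  cnt <- countReads(reads, ann, "s")
  asg <- assignReads(reads, ann)
  # conservation: every input read lands in exactly one category
  expect_equal(librarySize(cnt, "all"), length(reads))
  tab <- table(factor(asg$category,
                      c("sense", "antisense", "intergenic", "discarded")))
  expect_equal(sum(senseCounts(cnt)), unname(tab["sense"]))
  expect_equal(sum(antisenseCounts(cnt)), unname(tab["antisense"]))
  expect_equal(discardedCount(cnt), unname(tab["discarded"]))
  # per-gene tallies equal aggregation of per-read assignments
  for (cl in c("sense", "antisense")) {
    byGene <- table(asg$gene_id[asg$category == cl])
    got <- if (cl == "sense") senseCounts(cnt) else antisenseCounts(cnt)
    expect_equal(unname(got[names(byGene)]), unname(as.integer(byGene)))
    expect_true(all(got[setdiff(names(got), names(byGene))] == 0))
  }
})

test_that("empty read sets give all-zero counts", {
  ann <- miniAnnotation()
  cnt <- countReads(GRanges(), ann, "empty")
  expect_true(all(senseCounts(cnt) == 0))
  expect_true(all(antisenseCounts(cnt) == 0))
  expect_equal(discardedCount(cnt), 0L)
  expect_error(rpkmNormalize(cnt, ann), "library size")
})

test_that("RPKM follows the formula and its invariances", {
  set.seed(7)
  ann <- randomAnnotation(50)
  reads <- randomReads(4000, ann)
  cnt <- countReads(reads, ann, "s")
  et <- exprValues(rpkmNormalize(cnt, ann))
  lib <- librarySize(cnt)
  # independent one-line oracle
  expect_equal(et$rpkm, et$length^-1 * 1e9 / lib *
                 c(unname(senseCounts(cnt)), unname(antisenseCounts(cnt)),
                   unname(intergenicCounts(cnt))),
               tolerance = 1e-12)
  # scale invariance: duplicating every read doubles counts and library
  doubled <- exprValues(rpkmNormalize(countReads(rep(reads, 2), ann, "s"),
                                      ann))
  expect_equal(doubled$rpkm, et$rpkm, tolerance = 1e-12)
  # "all" library-size definition includes discarded reads
  expect_true(librarySize(cnt, "all") >= librarySize(cnt, "assigned"))
})

test_that("replicate averaging is the arithmetic mean", {
  a <- makeExpr(c(2, 0, 5)); b <- makeExpr(c(4, 1, 0))
  avg <- averageReplicates(list(a, b))
  expect_equal(exprValues(avg)$rpkm, c(3, 0.5, 2.5))
  expect_equal(nReplicates(avg), 2L)
  expect_equal(exprValues(averageReplicates(list(a)))$rpkm,
               exprValues(a)$rpkm)
  set.seed(1)
  ts <- lapply(1:5, function(i) makeExpr(runif(20)))
  expect_equal(exprValues(averageReplicates(ts))$rpkm,
               rowMeans(vapply(ts, function(t) exprValues(t)$rpkm,
                               numeric(20))))
  bad <- makeExpr(c(1, 2), ids = c("x", "y"))
  expect_error(averageReplicates(list(a, bad)), "mismatched")
})
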