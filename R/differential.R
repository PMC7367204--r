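## Differential calls and gene-set statistics.
##
## The differential rule is a fold-change cut-off with a noise floor, not
## a count-model test: a feature is "up" iff log2((mut+psi)/(wt+psi)) > 1
## AND max(mut, wt) > 1 RPKM ("down" symmetrically). Inequalities are
## strict, so a feature at exactly 2-fold (psi = 0) is unchanged. The
## pseudocount only guards division by zero; the floor is the noise
## control. No multiple-testing correction is applied to per-gene calls —
## corrections appear only in the enrichment statistics.

#' Call differential expression against wild type
#'
#' @param mutant,wildType Replicate-averaged [ExpressionTable-class]
#'   objects with identical feature sets.
#' @param foldThreshold Fold-change cut-off (> 1; default 2).
#' @param rpkmFloor Noise floor on `max(mut, wt)` RPKM (default 1).
#' @param pseudocount Added to both RPKM values before the ratio
#'   (default 0.1).
#' @return `data.frame` with one row per feature x class: `feature_id`,
#'   `class`, `wt_rpkm`, `mut_rpkm`, `log2_fc`, `max_rpkm`, `direction`
#'   (`up` / `down` / `unchanged`).
#' @export
callDifferential <- function(mutant, wildType, foldThreshold = 2,
                             rpkmFloor = 1, pseudocount = 0.1) {
  if (foldThreshold <= 1) stop("foldThreshold must be > 1")
  if (rpkmFloor < 0) stop("rpkmFloor must be >= 0")
  mt <- exprValues(mutant); wt <- exprValues(wildType)
  if (!identical(paste(mt$feature_id, mt$class),
                 paste(wt$feature_id, wt$class)))
    stop("mutant and wild-type tables have mismatched feature sets")
  lfc <- log2((mt$rpkm + pseudocount) / (wt$rpkm + pseudocount))
  mx <- pmax(mt$rpkm, wt$rpkm)
  cut <- log2(foldThreshold)
  direction <- rep("unchanged", nrow(mt))
  direction[lfc > cut & mx > rpkmFloor] <- "up"
  direction[lfc < -cut & mx > rpkmFloor] <- "down"
  data.frame(feature_id = mt$feature_id, class = mt$class,
             wt_rpkm = wt$rpkm, mut_rpkm = mt$rpkm, log2_fc = lfc,
             max_rpkm = mx, direction = direction,
             stringsAsFactors = FALSE)
}

#' Differentially-called gene ids for one class and direction
#'
#' @param calls Output of [callDifferential()].
#' @param class Strand class (default `"antisense"`).
#' @param direction Call direction (default `"up"`).
#' @return Character vector of feature ids.
#' @export
differentialSet <- function(calls, class = "antisense", direction = "up") {
  sort(calls$feature_id[calls$class == class & calls$direction == direction])
}

#' Fraction of protein-coding genes per call category
#'
#' Expresses call counts as percentages of the protein-coding gene
#' universe, per strand class and direction.
#'
#' @param calls Output of [callDifferential()].
#' @param nProteinCoding Size of the protein-coding universe.
#' @return `data.frame` with `class`, `direction`, `n`, `percent`.
#' @export
categoryFractions <- function(calls, nProteinCoding) {
  if (nProteinCoding <= 0) stop("empty protein-coding universe")
  combos <- expand.grid(direction = c("up", "down"),
                        class = c("sense", "antisense", "intergenic"),
                        stringsAsFactors = FALSE)[, c("class", "direction")]
  combos$n <- mapply(function(cl, d)
    sum(calls$class == cl & calls$direction == d),
    combos$class, combos$direction)
  combos$percent <- 100 * combos$n / nProteinCoding
  combos
}

#' Hypergeometric test for gene-set overlap
#'
#' Upper-tail probability `P[X >= |A intersect B|]` of the observed
#' overlap under random draws: population `|universe|`, successes `|A|`,
#' draws `|B|`. Both sets must be subsets of the universe.
#'
#' @param setA,setB Character vectors of feature ids.
#' @param universe Character vector defining the population.
#' @return List with `n_A`, `n_B`, `n_intersection`, `n_universe`,
#'   `p_value`.
#' @export
hypergeometricOverlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  k <- length(intersect(setA, setB))
  nA <- length(setA); nB <- length(setB); N <- length(universe)
  p <- phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE)
  lp <- phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE,
               log.p = TRUE) / log(10)
  list(n_A = nA, n_B = nB, n_intersection = k, n_universe = N,
       p_value = p, log10_p = lp)
}

## Mann-Whitney U (x vs y): U = #{(i,j): x_i > y_j} + 0.5 * #ties.
.uStatistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

.mannWhitneyExact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  mu <- n1 * n2 / 2
  obs <- .uStatistic(x, y)
  labelings <- combn(n1 + n2, n1)
  U <- apply(labelings, 2, function(idx)
    .uStatistic(pool[idx], pool[-idx]))
  eps <- sqrt(.Machine$double.eps)
  mean(abs(U - mu) >= abs(obs - mu) - eps)
}

.mannWhitneyApprox <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  obs <- .uStatistic(x, y)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 == 0) return(1)
  # continuity correction, as in the classical normal approximation
  z <- max(0, abs(obs - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-z))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact permutation distribution (all labelings, tie-aware) when both
#' sample sizes are at most `exactLimit`; otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y Numeric samples.
#' @param exactLimit Largest per-sample size for the exact path
#'   (default 8).
#' @return List with `U` (for `x` vs `y`), `p_value`, `method`.
#' @export
mannWhitneyTest <- function(x, y, exactLimit = 8L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- length(x) <= exactLimit && length(y) <= exactLimit
  p <- if (exact) .mannWhitneyExact(x, y) else .mannWhitneyApprox(x, y)
  list(U = .uStatistic(x, y), p_value = p,
       method = if (exact) "exact" else "normal_approx")
}

#' Synergy test: double-mutant vs single-mutant fold inductions
#'
#' Compares the distribution of per-gene antisense fold inductions in the
#' double perturbation against a single perturbation over a common gene
#' set (Mann-Whitney, two-sided), reporting both medians and their ratio.
#'
#' @param foldDouble,foldSingle Positive per-gene fold inductions.
#' @return List with `median_double`, `median_single`, `median_ratio`,
#'   `U`, `p_value`, `method`.
#' @export
synergyTest <- function(foldDouble, foldSingle) {
  if (!length(foldDouble) || !length(foldSingle))
    stop("both fold-induction sets must be non-empty")
  if (any(foldDouble <= 0) || any(foldSingle <= 0))
    stop("fold inductions must be positive (use a pseudocount upstream)")
  mw <- mannWhitneyTest(foldDouble, foldSingle)
  list(median_double = median(foldDouble),
       median_single = median(foldSingle),
       median_ratio = median(foldDouble) / median(foldSingle),
       U = mw$U, p_value = mw$p_value, method = mw$method)
}

#' Term enrichment by one-sided Fisher's exact test
#'
#' For each term, tests over-representation of the term's genes in
#' `geneSet` against the universe (2x2 table, `alternative = "greater"`),
#' with Bonferroni correction over the tested terms.
#'
#' @param geneSet Character vector of genes of interest.
#' @param termMap `data.frame` with columns `term` and `gene_id`.
#' @param universe Character vector; must contain all term genes.
#' @return `data.frame`, one row per term: table counts `a` (set & term),
#'   `b` (set only), `c` (term only), `d` (neither), `odds_ratio`,
#'   `p_value`, `p_adjusted`; sorted by `p_value`.
#' @export
termEnrichment <- function(geneSet, termMap, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (!all(termMap$gene_id %in% universe))
    stop("term map contains genes outside the universe")
  geneSet <- intersect(unique(geneSet), universe)
  terms <- sort(unique(termMap$term))
  res <- lapply(terms, function(tm) {
    tg <- unique(termMap$gene_id[termMap$term == tm])
    a <- length(intersect(geneSet, tg))
    b <- length(geneSet) - a
    cc <- length(tg) - a
    d <- length(universe) - a - b - cc
    ft <- fisher.test(matrix(c(a, b, cc, d), 2, 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(term = tm, a = a, b = b, c = cc, d = d,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_value, method = "bonferroni")
  out[order(out$p_value, out$term), , drop = FALSE]
}
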