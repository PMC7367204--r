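## Synthetic ChIP coverage tracks with spike-in read counts.
##
## Per-gene IP shape (added onto a flat background), oriented 5' -> 3':
##   - linear 5' ramp from 0 to the plateau over `rampLength` bp;
##   - gene-body plateau of height plateauScale * exprScore;
##   - optional Gaussian TSS-proximal peak;
##   - a cosine-tapered trough multiplying the gene's contribution
##     around the CPS (factor 1 - troughDepth at the centre, 1 at the
##     edges), emulating the dip in polymerase occupancy there;
##   - a short post-CPS plateau shoulder, then linear decay to zero —
##     so the trough has defined shoulders on both sides.
## Input tracks are flat. Spike-in is represented as scalar read counts
## per track (a fixed fraction of the track's total signal), which is
## all the normalization formula consumes.

#' ChIP generator configuration
#'
#' Shape parameters are shared across conditions unless overridden inside
#' a condition entry; each condition may additionally set `depthFactor`
#' (sequencing-depth multiplier applied to the IP) and `spikeFraction`.
#' Setting `troughDepth = 0` in a condition emulates the
#' effaced-CPS-trough regime seen when H2B ubiquitylation is lost.
#'
#' @param conditions Named list; each entry a list with optional
#'   overrides (`antibody`, `troughDepth`, `depthFactor`,
#'   `spikeFraction`, `tssPeakHeight`, ...).
#' @param inputLevel Flat input coverage level.
#' @param background IP background level outside genes.
#' @param plateauScale Plateau height per unit expression score.
#' @param exprMeanLog,exprSdLog Log-normal parameters of per-gene
#'   expression scores.
#' @param rampLength 5' ramp length (bp).
#' @param tssPeakHeight TSS peak height relative to the plateau.
#' @param tssPeakSd,tssPeakCenter Gaussian peak width and centre
#'   (bp downstream of the TSS).
#' @param troughDepth CPS trough depth in `[0, 1]` (0 = no trough).
#' @param cpsTroughHalfwidth Trough half-width (bp).
#' @param postCpsPlateau,postCpsDecay Post-CPS shoulder length and decay
#'   length (bp).
#' @param spikeFraction Spike-in reads as a fraction of a track's total
#'   signal.
#' @param depthFactor IP depth multiplier.
#' @return Configuration list for [simulateChip()].
#' @export
chipConfig <- function(conditions = list(
                         control = list(antibody = "RNAPII",
                                        troughDepth = 0.6),
                         h2bub1_deficient = list(antibody = "RNAPII",
                                                 troughDepth = 0)),
                       inputLevel = 20, background = 2,
                       plateauScale = 60,
                       exprMeanLog = 0, exprSdLog = 0.5,
                       rampLength = 150L,
                       tssPeakHeight = 0.5, tssPeakSd = 60,
                       tssPeakCenter = 100L,
                       troughDepth = 0.6, cpsTroughHalfwidth = 150L,
                       postCpsPlateau = 300L, postCpsDecay = 200L,
                       spikeFraction = 0.1, depthFactor = 1) {
  cfg <- list(conditions = conditions, inputLevel = inputLevel,
              background = background, plateauScale = plateauScale,
              exprMeanLog = exprMeanLog, exprSdLog = exprSdLog,
              rampLength = rampLength, tssPeakHeight = tssPeakHeight,
              tssPeakSd = tssPeakSd, tssPeakCenter = tssPeakCenter,
              troughDepth = troughDepth,
              cpsTroughHalfwidth = cpsTroughHalfwidth,
              postCpsPlateau = postCpsPlateau,
              postCpsDecay = postCpsDecay,
              spikeFraction = spikeFraction, depthFactor = depthFactor)
  num <- cfg[!(names(cfg) %in% c("conditions", "exprMeanLog"))]
  if (any(unlist(num) < 0)) stop("negative shape parameters are not allowed")
  if (cfg$troughDepth > 1) stop("troughDepth must lie in [0, 1]")
  cfg
}

.condShape <- function(cfg, cond) {
  shape <- cfg[setdiff(names(cfg), "conditions")]
  for (nm in names(cond)) shape[[nm]] <- cond[[nm]]
  if (!is.null(shape$troughDepth) &&
      (shape$troughDepth < 0 || shape$troughDepth > 1))
    stop("troughDepth must lie in [0, 1]")
  shape
}

## Contribution of one gene to the IP signal, as (positions, values).
.geneSignal <- function(tss, cps, strandChar, h, shape, chromLen) {
  dir <- if (strandChar == "+") 1L else -1L
  bodyLen <- abs(cps - tss) + 1L
  tailLen <- shape$postCpsPlateau + shape$postCpsDecay
  d <- seq_len(bodyLen + tailLen) - 1L        # distance downstream of TSS
  val <- h * pmin(1, d / max(1, shape$rampLength))
  val <- val + h * shape$tssPeakHeight *
    exp(-0.5 * ((d - shape$tssPeakCenter) / shape$tssPeakSd)^2)
  # decay over the tail beyond the post-CPS shoulder
  tail <- d - (bodyLen - 1L) - shape$postCpsPlateau
  decay <- pmax(0, pmin(1, 1 - tail / max(1, shape$postCpsDecay)))
  val <- val * ifelse(tail > 0, decay, 1)
  # flat-cored trough centred on the CPS: full depth over the inner
  # half-width, cosine taper to 1 at the edges
  hw <- shape$cpsTroughHalfwidth
  if (shape$troughDepth > 0 && hw > 0) {
    x <- abs(d - (bodyLen - 1L))
    w <- numeric(length(d))
    w[x <= hw / 2] <- 1
    taper <- x > hw / 2 & x <= hw
    w[taper] <- 0.5 * (1 + cos(pi * (x[taper] - hw / 2) / (hw / 2)))
    val <- val * (1 - shape$troughDepth * w)
  }
  pos <- tss + dir * d
  ok <- pos >= 1L & pos <= chromLen
  list(pos = pos[ok], val = val[ok])
}

#' Simulate spike-in ChIP coverage tracks
#'
#' Builds one per-base IP track and one flat input track per condition on
#' the given annotation's genome, plus integer spike-in read counts per
#' track. Per-gene plateau heights are proportional to log-normal
#' expression scores drawn once (shared across conditions, as befits a
#' set of parallel IPs from the same cells). Identical seed and
#' configuration give identical output.
#'
#' @param annotation A [GenomeAnnotation-class].
#' @param config From [chipConfig()].
#' @param seed Integer seed.
#' @return Named list per condition: `ip` and `input`
#'   ([CoverageTrack-class]), `ipSpikeReads`, `inputSpikeReads`,
#'   `antibody`, `shape` (resolved shape parameters) and `exprScores`.
#' @export
simulateChip <- function(annotation, config = chipConfig(), seed = 1L) {
  set.seed(seed)
  g <- genes(annotation)
  cs <- chromSizes(annotation)
  expr <- rlnorm(length(g), config$exprMeanLog, config$exprSdLog)
  tss <- .tssPositions(g); cps <- .cpsPositions(g)
  strandChar <- as.character(strand(g))
  chromOf <- as.character(seqnames(g))
  out <- list()
  for (condName in names(config$conditions)) {
    shape <- .condShape(config, config$conditions[[condName]])
    ip <- lapply(cs, function(len) rep(shape$background, len))
    for (i in seq_along(g)) {
      h <- shape$plateauScale * expr[i]
      sig <- .geneSignal(tss[i], cps[i], strandChar[i], h, shape,
                         cs[[chromOf[i]]])
      ip[[chromOf[i]]][sig$pos] <- ip[[chromOf[i]]][sig$pos] + sig$val
    }
    ip <- lapply(ip, function(v) v * shape$depthFactor)
    input <- lapply(cs, function(len) rep(shape$inputLevel, len))
    ipTotal <- sum(vapply(ip, sum, numeric(1)))
    inputTotal <- sum(vapply(input, sum, numeric(1)))
    out[[condName]] <- list(
      ip = CoverageTrack(ip, 1L, sprintf("%s_%s_ip",
                                         shape$antibody %||% "IP", condName)),
      input = CoverageTrack(input, 1L, sprintf("%s_input", condName)),
      ipSpikeReads = max(1L, as.integer(round(shape$spikeFraction * ipTotal))),
      inputSpikeReads = max(1L, as.integer(round(shape$spikeFraction *
                                                   inputTotal))),
      antibody = shape$antibody %||% "IP",
      shape = shape, exprScores = expr)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete dataset (RNA-seq + ChIP)
#'
#' Runs [simulateRnaSeq()] and [simulateChip()] on the same toy genome
#' and returns the combined [SyntheticDataset-class].
#'
#' @param rnaConfig From [rnaSeqConfig()].
#' @param chipCfg From [chipConfig()].
#' @param seed Integer seed (shared by both generators).
#' @return A [SyntheticDataset-class].
#' @export
simulateDataset <- function(rnaConfig = rnaSeqConfig(),
                            chipCfg = chipConfig(), seed = 1L) {
  ds <- simulateRnaSeq(rnaConfig, seed)
  ds@chip <- simulateChip(ds@annotation, chipCfg, seed)
  ds@config$chip <- chipCfg
  validObject(ds)
  ds
}
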