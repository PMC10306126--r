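## Synthetic-data generators with known ground truth. Counts are rounded
## exponentiated Gaussians (log-normal), not Poisson mixtures: the pipeline
## analyses log10(x+1), so planting correlation structure on the log scale
## keeps the planted effect sizes interpretable downstream.

#' Specification of a block-correlated synthetic Fos count table
#'
#' Regions are partitioned into blocks (the ground-truth modules). On the
#' log10 scale, region values are multivariate normal with correlation
#' `withinR` inside a block and `betweenR` between blocks. The treatment
#' group additionally receives `globalRBoost` added to every off-diagonal
#' correlation (capped at 0.999) — a global-synchrony knob emulating the
#' brain-wide coactivation increase seen in withdrawal, which lowers the
#' module count recovered by the half-height cut.
#'
#' @param blockSizes integer vector of block sizes; their sum is the number
#'   of regions.
#' @param withinR target within-block correlation, in [0, 1); must exceed
#'   `betweenR`.
#' @param betweenR target between-block correlation.
#' @param globalRBoost additive synchrony term for the treatment condition.
#' @param nSubjectsPerGroup subjects per group (the study design used 4-5).
#' @param baseLogMean mean of the log10 counts (2 = a typical region with
#'   ~100 Fos+ cells).
#' @param logSd standard deviation of the log10 counts.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A list of class `"SyntheticCountSpec"`.
#' @export
syntheticCountSpec <- function(blockSizes = c(20L, 20L, 20L),
                               withinR = 0.9, betweenR = 0.1,
                               globalRBoost = 0,
                               nSubjectsPerGroup = 5L,
                               baseLogMean = 2, logSd = 0.4,
                               seed = 1L) {
  stopifnot(length(blockSizes) >= 1L, all(blockSizes >= 1L))
  if (!(withinR >= 0 && withinR < 1))
    stop("withinR must lie in [0, 1)")
  if (withinR <= betweenR)
    stop("withinR (", withinR, ") must exceed betweenR (", betweenR, ")")
  if (nSubjectsPerGroup < 2L)
    stop("need at least 2 subjects per group")
  structure(list(blockSizes = as.integer(blockSizes),
                 nRegions = sum(as.integer(blockSizes)),
                 withinR = withinR, betweenR = betweenR,
                 globalRBoost = globalRBoost,
                 nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
                 baseLogMean = baseLogMean, logSd = logSd,
                 seed = as.integer(seed)),
            class = "SyntheticCountSpec")
}

.blockCorrelation <- function(blockSizes, withinR, betweenR, boost = 0) {
  n <- sum(blockSizes)
  block <- rep(seq_along(blockSizes), blockSizes)
  C <- matrix(betweenR, n, n)
  same <- outer(block, block, "==")
  C[same] <- withinR
  if (boost != 0) C <- pmin(C + boost, 0.999)
  diag(C) <- 1
  C
}

.checkPSD <- function(C, what) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("requested ", what, " correlation matrix is not positive ",
         "semi-definite (min eigenvalue ", signif(min(ev), 3),
         "); choose feasible withinR/betweenR/globalRBoost")
  invisible(TRUE)
}

.drawCounts <- function(C, n, mu, sd) {
  z <- MASS::mvrnorm(n, mu = rep(0, ncol(C)), Sigma = C, tol = 1e-6)
  x <- mu + sd * t(z)                      # regions x subjects, log10 scale
  pmax(round(10^x - 1), 0)
}

#' Generate a synthetic Fos count table with known modules
#'
#' Draws log10-scale region values from the block-structured multivariate
#' normal defined by the spec, exponentiates, subtracts the +1 offset used
#' by the downstream normalisation and rounds to non-negative integer
#' counts. Both groups share the block assignment; the treatment group's
#' correlation target carries the global boost. An infeasible correlation
#' target (non-PSD) is an error, never silently repaired.
#'
#' @param spec a [syntheticCountSpec()].
#' @return list with `experiment` (a [FosExperiment-class]) and `truth`
#'   (named integer vector region -> block, plus the two target
#'   correlation matrices).
#' @export
generateCounts <- function(spec) {
  stopifnot(inherits(spec, "SyntheticCountSpec"))
  C0 <- .blockCorrelation(spec$blockSizes, spec$withinR, spec$betweenR)
  C1 <- .blockCorrelation(spec$blockSizes, spec$withinR, spec$betweenR,
                          boost = spec$globalRBoost)
  .checkPSD(C0, "control")
  .checkPSD(C1, "treatment")
  regions <- sprintf("R%03d", seq_len(spec$nRegions))
  dimnames(C0) <- dimnames(C1) <- list(regions, regions)
  set.seed(spec$seed)
  n <- spec$nSubjectsPerGroup
  ctrl <- .drawCounts(C0, n, spec$baseLogMean, spec$logSd)
  trt <- .drawCounts(C1, n, spec$baseLogMean, spec$logSd)
  m <- cbind(ctrl, trt)
  rownames(m) <- regions
  colnames(m) <- c(sprintf("ctrl%02d", seq_len(n)),
                   sprintf("trt%02d", seq_len(n)))
  grp <- c(rep("control", n), rep("treatment", n))
  fe <- suppressWarnings(FosExperiment(m, group = grp))
  block <- rep(seq_along(spec$blockSizes), spec$blockSizes)
  names(block) <- regions
  list(experiment = fe,
       truth = list(moduleOfRegion = block,
                    controlCorrelation = C0,
                    treatmentCorrelation = C1))
}

#' Specification of a synthetic expression matrix with planted signal genes
#'
#' Signal genes are built to correlate (target `signalRho`) with a supplied
#' per-region log-fold-change vector; null genes are independent noise.
#' Each gene contributes `nExperimentsPerGene` replicate experiments whose
#' values are the gene's latent regional profile plus experiment noise,
#' affinely mapped onto the non-negative "percentage of pixels" scale.
#'
#' @param nNullGenes number of null genes.
#' @param nSignalGenes number of planted signal genes.
#' @param signalRho target correlation with the LFC vector, |rho| < 1.
#' @param noiseSd per-experiment noise SD (on the latent z scale).
#' @param nExperimentsPerGene replicate experiments per gene.
#' @param seed integer seed.
#' @return A list of class `"SyntheticExpressionSpec"`.
#' @export
syntheticExpressionSpec <- function(nNullGenes = 2000L,
                                    nSignalGenes = 200L,
                                    signalRho = 0.4,
                                    noiseSd = 0.3,
                                    nExperimentsPerGene = 1L,
                                    seed = 1L) {
  if (abs(signalRho) >= 1) stop("|signalRho| must be < 1")
  stopifnot(nNullGenes >= 0L, nSignalGenes >= 0L,
            nExperimentsPerGene >= 1L, noiseSd >= 0)
  structure(list(nNullGenes = as.integer(nNullGenes),
                 nSignalGenes = as.integer(nSignalGenes),
                 signalRho = signalRho, noiseSd = noiseSd,
                 nExperimentsPerGene = as.integer(nExperimentsPerGene),
                 seed = as.integer(seed)),
            class = "SyntheticExpressionSpec")
}

#' Generate synthetic expression data against a known LFC vector
#'
#' @param spec a [syntheticExpressionSpec()].
#' @param lfc named per-region log-fold-change vector (e.g. from
#'   [fosLfc()]); must have non-zero variance.
#' @return list with `expression` (a [RegionalExpression-class]) and
#'   `truth` (signal gene ids and the realised per-gene correlation of the
#'   aggregated profile with `lfc`).
#' @export
generateExpression <- function(spec, lfc) {
  stopifnot(inherits(spec, "SyntheticExpressionSpec"))
  if (is.null(names(lfc))) stop("lfc must be named by region")
  if (stats::sd(lfc) == 0)
    stop("lfc has zero variance; correlation with it is undefined")
  nR <- length(lfc)
  zl <- as.numeric(scale(lfc))
  set.seed(spec$seed)
  genes <- c(if (spec$nSignalGenes)
    sprintf("sig%04d", seq_len(spec$nSignalGenes)),
    if (spec$nNullGenes) sprintf("null%04d", seq_len(spec$nNullGenes)))
  nG <- length(genes)
  isSignal <- grepl("^sig", genes)
  rho <- spec$signalRho
  ## latent per-gene regional profile (unit-variance z scale)
  latent <- matrix(stats::rnorm(nG * nR), nG, nR)
  if (any(isSignal))
    latent[isSignal, ] <- rho * matrix(zl, sum(isSignal), nR, byrow = TRUE) +
      sqrt(1 - rho^2) * latent[isSignal, , drop = FALSE]
  nE <- spec$nExperimentsPerGene
  dens <- matrix(0, nG * nE, nR,
                 dimnames = list(NULL, names(lfc)))
  gene <- rep(genes, each = nE)
  for (e in seq_len(nE)) {
    obs <- latent + spec$noiseSd * matrix(stats::rnorm(nG * nR), nG, nR)
    dens[seq(e, nG * nE, by = nE), ] <- obs
  }
  ## affine map to the non-negative percentage-of-pixels scale; clipping is
  ## ~5 sigma out so it essentially never distorts planted correlations
  dens <- pmin(pmax(50 + 10 * dens, 0), 100)
  rownames(dens) <- sprintf("%s_e%d", gene, rep(seq_len(nE), times = nG))
  expr <- RegionalExpression(dens, gene)
  realized <- apply(latent, 1L, function(v) stats::cor(v, lfc))
  names(realized) <- genes
  list(expression = expr,
       truth = list(signalGeneIds = genes[isSignal],
                    realizedRho = realized))
}
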