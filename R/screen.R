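## Brain-wide expression screen: correlate each gene's baseline regional
## expression density with the treatment-vs-control Fos log-fold change,
## test each correlation, and control the FDR by Benjamini-Hochberg.

#' Regional Fos log-fold change
#'
#' Per region, the mean of log10(count+1) over treatment subjects minus
#' the mean over control subjects (equivalently log10 of the ratio of
#' geometric means of count+1).
#'
#' @param fe a [FosExperiment-class] with both groups present.
#' @param excludedRegions region acronyms to drop (e.g. the frontal pole
#'   outlier; see [runConfig()]).
#' @return named numeric vector (one value per retained region).
#' @export
fosLfc <- function(fe, excludedRegions = character()) {
  grp <- subjectGroups(fe)
  if (!all(c("control", "treatment") %in% grp))
    stop("both groups must be present to compute a log-fold change")
  m <- logCounts(fe)
  lfc <- rowMeans(m[, grp == "treatment", drop = FALSE]) -
    rowMeans(m[, grp == "control", drop = FALSE])
  lfc[setdiff(names(lfc), excludedRegions)]
}

#' Aggregate expression experiments per gene
#'
#' Each experiment's regional vector is centred to mean 0 and scaled to
#' unit SD over the shared region set, then averaged across that gene's
#' experiments — so replicate in-situ experiments that are affine
#' transforms of one another contribute identically. Zero-variance
#' experiments are dropped with a warning; a gene with no usable
#' experiment is excluded.
#'
#' @param expr a [RegionalExpression-class].
#' @param regions optional region subset (default: all columns).
#' @return gene x region numeric matrix of aggregated z-profiles.
#' @export
aggregateExpression <- function(expr, regions = NULL) {
  stopifnot(is(expr, "RegionalExpression"))
  d <- expr@density
  if (!is.null(regions)) {
    missing <- setdiff(regions, colnames(d))
    if (length(missing))
      stop("region(s) absent from expression matrix: ",
           paste(missing, collapse = ", "))
    d <- d[, regions, drop = FALSE]
  }
  sds <- apply(d, 1L, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    warning("dropping zero-variance experiment(s): ",
            paste(rownames(d)[zero], collapse = ", "), call. = FALSE)
    d <- d[!zero, , drop = FALSE]
  }
  genes <- expr@gene[!zero]
  if (!nrow(d)) stop("no usable experiments after zero-variance filtering")
  z <- t(scale(t(d)))                      # per-experiment z-profiles
  agg <- rowsum(z, group = genes)
  tab <- table(genes)
  agg <- agg / as.vector(tab[rownames(agg)])
  lost <- setdiff(unique(expr@gene), rownames(agg))
  if (length(lost))
    message("gene(s) excluded (no usable experiments): ",
            paste(lost, collapse = ", "))
  agg
}

#' Pearson correlation test of gene profiles against the LFC vector
#'
#' For each gene (row), the Pearson r with the LFC vector over the shared
#' regions and a two-sided p-value from t = r*sqrt((n-2)/(1-r^2)) on n-2
#' degrees of freedom. Zero-variance gene profiles are untestable (NA p)
#' and excluded from the FDR denominator downstream.
#'
#' @param geneMat gene x region matrix (rows named by gene).
#' @param lfc named per-region LFC vector covering the matrix columns.
#' @return data.frame with columns `gene`, `r`, `p`, `n_regions_used`.
#' @export
correlateGenes <- function(geneMat, lfc) {
  shared <- intersect(colnames(geneMat), names(lfc))
  if (length(shared) < 3L)
    stop("need at least 3 shared regions (have ", length(shared), ")")
  m <- geneMat[, shared, drop = FALSE]
  y <- lfc[shared]
  n <- length(shared)
  if (stats::sd(y) == 0) stop("LFC vector has zero variance")
  sds <- apply(m, 1L, stats::sd)
  r <- rep(NA_real_, nrow(m))
  ok <- sds > 0
  if (any(ok))
    r[ok] <- as.numeric(stats::cor(t(m[ok, , drop = FALSE]), y))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.na(r) & abs(r) >= 1] <- 0
  data.frame(gene = rownames(m), r = r, p = p,
             n_regions_used = n, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values via [stats::p.adjust()]; significance at
#' `q <= level`.
#'
#' @param p numeric p-values (NA allowed; excluded from the denominator).
#' @param level nominal FDR level.
#' @return data.frame with columns `p`, `q`, `significant`.
#' @export
bhFdr <- function(p, level = 0.05) {
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q,
             significant = !is.na(q) & q <= level)
}

#' Run the expression-vs-Fos-change screen
#'
#' Composes [fosLfc()] (with the configured region exclusions),
#' [aggregateExpression()], [correlateGenes()] and [bhFdr()]. The realised
#' |r| significance frontier — the smallest |r| among significant genes —
#' is reported in the run log.
#'
#' @param expr a [RegionalExpression-class].
#' @param fe a [FosExperiment-class].
#' @param config a [RunConfig-class]; `fdrLevel` and `excludedRegions`
#'   are used.
#' @return data.frame (gene, r, p, q, significant, n_regions_used) sorted
#'   by |r| descending; attribute `"frontier"` holds the realised |r|
#'   frontier (NA when nothing is significant).
#' @export
runScreen <- function(expr, fe, config = runConfig()) {
  lfc <- fosLfc(fe, excludedRegions = config@excludedRegions)
  shared <- intersect(colnames(expr@density), names(lfc))
  if (length(shared) < 3L)
    stop("fewer than 3 regions shared between expression data and counts")
  agg <- aggregateExpression(expr, regions = shared)
  res <- correlateGenes(agg, lfc)
  fdr <- bhFdr(res$p, level = config@fdrLevel)
  res$q <- fdr$q
  res$significant <- fdr$significant
  res <- res[order(-abs(res$r)), ]
  rownames(res) <- NULL
  frontier <- if (any(res$significant))
    min(abs(res$r[res$significant])) else NA_real_
  .stageLog("screen", sum(res$significant), " of ",
            sum(!is.na(res$p)), " testable genes significant at q <= ",
            config@fdrLevel, "; |r| frontier = ",
            if (is.na(frontier)) "NA" else signif(frontier, 3))
  out <- res[, c("gene", "r", "p", "q", "significant", "n_regions_used")]
  attr(out, "frontier") <- frontier
  out
}
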