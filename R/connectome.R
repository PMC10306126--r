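## Functional connectome construction: log10(x+1) normalisation, per-group
## region-by-region Pearson correlation, Euclidean distances between
## correlation rows, and module detection by cutting the complete-linkage
## dendrogram at half of its maximum merge height.

#' Log-normalise Fos counts
#'
#' Adds an assay `"lognorm"` holding `log10(count + 1)`; the +1 offset
#' keeps zero counts defined (and mapped to exactly 0).
#'
#' @param fe a [FosExperiment-class].
#' @return the same object with the `"lognorm"` assay attached.
#' @examples
#' sim <- generateCounts(syntheticCountSpec(blockSizes = c(3, 3)))
#' fe <- normalizeCounts(sim$experiment)
#' @export
normalizeCounts <- function(fe) {
  stopifnot(is(fe, "FosExperiment"))
  SummarizedExperiment::assay(fe, "lognorm") <- log10(fosCounts(fe) + 1)
  fe
}

#' Log-normalised values
#'
#' @param fe a [FosExperiment-class]; normalised on the fly if needed.
#' @return region x subject matrix of log10(count+1).
#' @export
logCounts <- function(fe) {
  if (!"lognorm" %in% SummarizedExperiment::assayNames(fe))
    fe <- normalizeCounts(fe)
  SummarizedExperiment::assay(fe, "lognorm")
}

#' Region-by-region Pearson correlation within one group
#'
#' Correlates every pair of regions' log10(count+1) values across the
#' subjects of one group. Regions whose values have zero variance within
#' the group (Pearson undefined) are excluded with a warning and recorded
#' in the result's `dropped` slot.
#'
#' @param fe a [FosExperiment-class].
#' @param group `"control"` or `"treatment"`.
#' @return A [CorrelationMatrix-class].
#' @export
correlationMatrix <- function(fe, group = c("control", "treatment")) {
  group <- match.arg(group)
  keepSubj <- subjectGroups(fe) == group
  if (sum(keepSubj) < 2L)
    stop("need at least 2 subjects in group '", group, "'")
  m <- logCounts(fe)[, keepSubj, drop = FALSE]
  v <- apply(m, 1L, stats::var)
  zero <- v == 0
  if (all(zero))
    stop("all regions have zero variance in group '", group, "'")
  if (any(zero)) {
    warning("excluding zero-variance region(s) in group '", group, "': ",
            paste(rownames(m)[zero], collapse = ", "), call. = FALSE)
    m <- m[!zero, , drop = FALSE]
  }
  r <- stats::cor(t(m))
  diag(r) <- 1
  new("CorrelationMatrix", r = r, group = group,
      dropped = rownames(logCounts(fe))[zero])
}

#' Euclidean distances between correlation-matrix rows
#'
#' The functional distance between regions i and j is the Euclidean norm of
#' the difference of their full correlation rows (including the unit
#' diagonal entries), i.e. regions are embedded by their correlation
#' profile to the whole brain.
#'
#' @param corr a [CorrelationMatrix-class].
#' @return A [stats::dist] object.
#' @export
correlationDistance <- function(corr) {
  stopifnot(is(corr, "CorrelationMatrix"))
  stats::dist(corr@r, method = "euclidean")
}

#' Module detection by the half-height dendrogram cut
#'
#' Hierarchically clusters the functional distances (complete linkage by
#' default) and cuts the dendrogram at `cutFraction` of its maximum merge
#' height; the connected subtrees below the cut are the modules. Module
#' ids are numbered by dendrogram leaf order. A single region yields one
#' module with cut height 0.
#'
#' @param d a [stats::dist] from [correlationDistance()], or a
#'   [CorrelationMatrix-class] (distances computed internally).
#' @param config a [RunConfig-class]; `linkageMethod` and `cutFraction`
#'   are used.
#' @return A [ModulePartition-class].
#' @export
clusterModules <- function(d, config = runConfig()) {
  if (is(d, "CorrelationMatrix")) d <- correlationDistance(d)
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1L) {
    mods <- stats::setNames(1L, labels)
    return(new("ModulePartition", modules = mods, nModules = 1L,
               cutHeight = 0, tree = NULL))
  }
  hc <- stats::hclust(d, method = config@linkageMethod)
  h <- config@cutFraction * max(hc$height)
  raw <- stats::cutree(hc, h = h)
  ## renumber so module 1 holds the leftmost dendrogram leaf, etc.
  leafOrderIds <- unique(raw[hc$order])
  mods <- stats::setNames(match(raw, leafOrderIds), names(raw))
  new("ModulePartition", modules = as.integer(mods) |>
        stats::setNames(names(raw)),
      nModules = length(leafOrderIds), cutHeight = h, tree = hc)
}
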