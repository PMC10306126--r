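#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## ---- RunConfig -------------------------------------------------------------

#' Run configuration for the connectome pipeline
#'
#' Holds the tunable parameters shared by every stage: the correlation
#' threshold defining a functional connection, the agglomeration method and
#' cut fraction for module detection, the hub-list depth, the FDR level for
#' the gene screen, and regions excluded from the screen (the frontal pole,
#' an expression-density outlier, by default).
#'
#' @slot correlationThreshold numeric in (0,1); edge iff r is strictly above it.
#' @slot linkageMethod character; any method accepted by [stats::hclust()].
#' @slot cutFraction numeric in (0,1); dendrogram cut at this fraction of the
#'   maximum merge height (0.5 = half-height).
#' @slot hubTopK integer; depth of the degree/betweenness/participation
#'   top lists used for hub calls (ties at the k-th value are kept).
#' @slot fdrLevel numeric in (0,1); Benjamini-Hochberg level for the screen.
#' @slot excludedRegions character; region acronyms dropped from the gene
#'   screen.
#' @slot rngSeed integer seed for stages that draw random numbers.
#' @export
setClass("RunConfig", representation(
  correlationThreshold = "numeric",
  linkageMethod = "character",
  cutFraction = "numeric",
  hubTopK = "integer",
  fdrLevel = "numeric",
  excludedRegions = "character",
  rngSeed = "integer"
))

setValidity("RunConfig", function(object) {
  msg <- character()
  th <- object@correlationThreshold
  if (length(th) != 1L || is.na(th) || th <= 0 || th > 1)
    msg <- c(msg, "correlationThreshold must be a single value in (0, 1]")
  cf <- object@cutFraction
  if (length(cf) != 1L || is.na(cf) || cf <= 0 || cf >= 1)
    msg <- c(msg, "cutFraction must be a single value in (0, 1)")
  fl <- object@fdrLevel
  if (length(fl) != 1L || is.na(fl) || fl <= 0 || fl >= 1)
    msg <- c(msg, "fdrLevel must be a single value in (0, 1)")
  if (length(object@hubTopK) != 1L || is.na(object@hubTopK) ||
      object@hubTopK < 1L)
    msg <- c(msg, "hubTopK must be a single integer >= 1")
  if (length(object@linkageMethod) != 1L)
    msg <- c(msg, "linkageMethod must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param correlationThreshold edge threshold on Pearson r (strict `>`).
#' @param linkageMethod agglomeration method for [stats::hclust()].
#' @param cutFraction fraction of the maximum merge height at which the
#'   dendrogram is cut.
#' @param hubTopK depth of the top-k centrality lists.
#' @param fdrLevel nominal false-discovery rate for the gene screen.
#' @param excludedRegions region acronyms excluded from the gene screen
#'   ("FRP", the frontal pole cerebral cortex, by default).
#' @param rngSeed integer seed.
#' @return A validated [RunConfig-class] object.
#' @examples
#' cfg <- runConfig(hubTopK = 10)
#' @export
runConfig <- function(correlationThreshold = 0.75,
                      linkageMethod = "complete",
                      cutFraction = 0.5,
                      hubTopK = 20L,
                      fdrLevel = 0.05,
                      excludedRegions = "FRP",
                      rngSeed = 1L) {
  new("RunConfig",
      correlationThreshold = as.numeric(correlationThreshold),
      linkageMethod = as.character(linkageMethod),
      cutFraction = as.numeric(cutFraction),
      hubTopK = as.integer(hubTopK),
      fdrLevel = as.numeric(fdrLevel),
      excludedRegions = as.character(excludedRegions),
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n",
      "  correlationThreshold: ", object@correlationThreshold, "\n",
      "  linkageMethod:        ", object@linkageMethod, "\n",
      "  cutFraction:          ", object@cutFraction, "\n",
      "  hubTopK:              ", object@hubTopK, "\n",
      "  fdrLevel:             ", object@fdrLevel, "\n",
      "  excludedRegions:      ",
      paste(object@excludedRegions, collapse = ", "), "\n",
      "  rngSeed:              ", object@rngSeed, "\n", sep = "")
})

## ---- FosExperiment ---------------------------------------------------------

#' Regional Fos counts with group labels
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] whose rows are brain
#' regions (Allen-atlas acronyms), columns are subjects, the `"counts"` assay
#' holds non-negative integer Fos-positive cell counts, and `colData(x)$group`
#' assigns every subject to `"control"` or `"treatment"`. Optional region
#' metadata (full name, anatomic group, cholinergic group, subsystem) lives
#' in `rowData`.
#'
#' @export
setClass("FosExperiment", contains = "SummarizedExperiment")

setValidity("FosExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msg <- c(msg, "counts must have region rownames and subject colnames")
  if (anyDuplicated(rownames(cts)))
    msg <- c(msg, paste0("duplicate region id(s): ",
                         paste(unique(rownames(cts)[duplicated(rownames(cts))]),
                               collapse = ", ")))
  if (anyDuplicated(colnames(cts)))
    msg <- c(msg, "duplicate subject id(s)")
  if (any(is.na(cts)))
    msg <- c(msg, "missing counts are not allowed")
  else {
    if (any(cts < 0))
      msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts - round(cts)) > 1e-8))
      msg <- c(msg, "counts must be integral")
  }
  grp <- SummarizedExperiment::colData(object)$group
  if (is.null(grp)) {
    msg <- c(msg, "colData must contain a 'group' column")
  } else {
    grp <- as.character(grp)
    if (any(is.na(grp)))
      msg <- c(msg, paste0("subject(s) without a group: ",
                           paste(colnames(cts)[is.na(grp)], collapse = ", ")))
    bad <- setdiff(stats::na.omit(unique(grp)), c("control", "treatment"))
    if (length(bad))
      msg <- c(msg, paste0("unknown group label(s): ",
                           paste(bad, collapse = ", ")))
    tab <- table(factor(grp, levels = c("control", "treatment")))
    if (any(tab < 2L))
      msg <- c(msg, "each group needs at least 2 subjects (correlation undefined otherwise)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FosExperiment
#'
#' @param counts region x subject matrix of non-negative integer Fos counts,
#'   with region acronyms as rownames and subject ids as colnames.
#' @param group character vector (or factor) of `"control"`/`"treatment"`
#'   labels, one per subject; may be named by subject id.
#' @param regionData optional data.frame/DataFrame of per-region metadata
#'   (as read by [readRegionMetadata()]); matched to rows by `region_id`.
#' @return A validated [FosExperiment-class].
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(c("MS", "NDB", "SI"), paste0("s", 1:4)))
#' fe <- FosExperiment(m, group = c("control", "control", "treatment", "treatment"))
#' @export
FosExperiment <- function(counts, group, regionData = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(group)) && !is.null(colnames(counts))) {
    missing <- setdiff(colnames(counts), names(group))
    if (length(missing))
      stop("subject(s) without a group assignment: ",
           paste(missing, collapse = ", "))
    group <- group[colnames(counts)]
  }
  cd <- S4Vectors::DataFrame(group = as.character(group),
                             row.names = colnames(counts))
  rd <- NULL
  if (!is.null(regionData)) {
    regionData <- as.data.frame(regionData)
    idx <- match(rownames(counts), regionData$region_id)
    rd <- S4Vectors::DataFrame(regionData[idx, , drop = FALSE],
                               row.names = rownames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    rowData = if (is.null(rd)) S4Vectors::DataFrame(row.names = rownames(counts)) else rd)
  obj <- new("FosExperiment", se)
  validObject(obj)
  tab <- table(subjectGroups(obj))
  if (any(tab < 4L))
    warning("fewer than 4 subjects in group(s): ",
            paste(names(tab)[tab < 4L], collapse = ", "),
            " - correlations will be noisy", call. = FALSE)
  obj
}

#' Accessors for FosExperiment
#'
#' `fosCounts()` returns the counts matrix, `regionIds()` the region
#' acronyms, `subjectIds()` the subject ids and `subjectGroups()` the named
#' group vector.
#'
#' @param x a [FosExperiment-class].
#' @return matrix or character vector as appropriate.
#' @rdname fosAccessors
#' @export
fosCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname fosAccessors
#' @export
regionIds <- function(x) rownames(x)

#' @rdname fosAccessors
#' @export
subjectIds <- function(x) colnames(x)

#' @rdname fosAccessors
#' @export
subjectGroups <- function(x) {
  g <- as.character(SummarizedExperiment::colData(x)$group)
  names(g) <- colnames(x)
  g
}

## ---- CorrelationMatrix -----------------------------------------------------

#' Per-group region-by-region Pearson correlation matrix
#'
#' @slot r symmetric numeric matrix with unit diagonal, entries in [-1, 1];
#'   dimnames are region acronyms.
#' @slot group the group label the correlations were computed in.
#' @slot dropped region acronyms excluded because their counts had zero
#'   variance within the group.
#' @export
setClass("CorrelationMatrix", representation(
  r = "matrix", group = "character", dropped = "character"))

setValidity("CorrelationMatrix", function(object) {
  r <- object@r
  msg <- character()
  if (nrow(r) != ncol(r) || is.null(rownames(r)) ||
      !identical(rownames(r), colnames(r)))
    return("r must be square with matching region dimnames")
  if (any(is.na(r)))
    msg <- c(msg, "r contains NA (zero-variance region not excluded?)")
  else {
    if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "r must be symmetric")
    if (max(abs(diag(r) - 1)) > 1e-8) msg <- c(msg, "diagonal must be 1")
    if (any(r < -1 - 1e-8) || any(r > 1 + 1e-8))
      msg <- c(msg, "entries must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn CorrelationMatrix-class the correlation matrix itself.
#' @param x,object a `CorrelationMatrix`.
#' @export
corValues <- function(x) x@r

setMethod("show", "CorrelationMatrix", function(object) {
  cat("CorrelationMatrix (", object@group, "): ",
      nrow(object@r), " regions", sep = "")
  if (length(object@dropped))
    cat("; dropped (zero variance): ",
        paste(object@dropped, collapse = ", "), sep = "")
  cat("\n")
})

## ---- ModulePartition -------------------------------------------------------

#' Region-to-module assignment from the half-height dendrogram cut
#'
#' @slot modules named integer vector, region -> module id; ids are numbered
#'   by dendrogram leaf order.
#' @slot nModules number of distinct modules.
#' @slot cutHeight height at which the dendrogram was cut
#'   (cutFraction x maximum merge height; 0 for a single region).
#' @slot tree the [stats::hclust] merge tree, or NULL for a single region.
#' @export
setClass("ModulePartition", representation(
  modules = "integer", nModules = "integer",
  cutHeight = "numeric", tree = "ANY"))

setValidity("ModulePartition", function(object) {
  m <- object@modules
  msg <- character()
  if (is.null(names(m)) || anyDuplicated(names(m)))
    msg <- c(msg, "modules must be uniquely named by region")
  if (any(is.na(m))) msg <- c(msg, "every region must be assigned a module")
  if (length(unique(m)) != object@nModules)
    msg <- c(msg, "nModules must equal the number of distinct labels")
  if (length(msg)) msg else TRUE
})

#' @describeIn ModulePartition-class named region -> module vector.
#' @param x,object a `ModulePartition`.
#' @export
moduleAssignments <- function(x) x@modules

#' @describeIn ModulePartition-class number of modules.
#' @export
nModules <- function(x) x@nModules

#' @describeIn ModulePartition-class the cut height used.
#' @export
cutHeight <- function(x) x@cutHeight

setMethod("show", "ModulePartition", function(object) {
  cat("ModulePartition: ", length(object@modules), " regions in ",
      object@nModules, " modules (cut height ",
      signif(object@cutHeight, 4), ")\n", sep = "")
})

## ---- ThresholdedNetwork ----------------------------------------------------

#' Binary functional-connectivity graph
#'
#' Undirected, unweighted graph whose edges are region pairs with Pearson
#' r strictly above the threshold. Backed by an [igraph::igraph] object;
#' edge weights carry the original r for export but all metrics treat the
#' graph as binary.
#'
#' @slot graph an igraph object with region-named vertices.
#' @slot threshold the correlation threshold used.
#' @export
setClass("ThresholdedNetwork", representation(
  graph = "ANY", threshold = "numeric"))

setValidity("ThresholdedNetwork", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g)) return("graph must be an igraph object")
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops are not allowed")
  if (is.null(igraph::V(g)$name)) msg <- c(msg, "vertices must be named")
  if (length(msg)) msg else TRUE
})

#' @describeIn ThresholdedNetwork-class the underlying igraph object.
#' @param x,object a `ThresholdedNetwork`.
#' @export
networkGraph <- function(x) x@graph

#' @describeIn ThresholdedNetwork-class region names of the nodes.
#' @export
networkRegions <- function(x) igraph::V(x@graph)$name

#' @describeIn ThresholdedNetwork-class number of edges.
#' @export
edgeCount <- function(x) igraph::ecount(x@graph)

setMethod("show", "ThresholdedNetwork", function(object) {
  cat("ThresholdedNetwork: ", igraph::vcount(object@graph), " regions, ",
      igraph::ecount(object@graph), " edges (r > ",
      object@threshold, ")\n", sep = "")
})

## ---- RegionalExpression ----------------------------------------------------

#' Gene expression density across brain regions
#'
#' Holds one row per in-situ experiment (a gene may have several), columns
#' are regions, and values are expression densities on the
#' "percentage of pixels" scale (non-negative, nominally 0-100).
#'
#' @slot density experiment x region numeric matrix, rownames are
#'   experiment ids.
#' @slot gene character vector, one gene symbol per experiment row.
#' @export
setClass("RegionalExpression", representation(
  density = "matrix", gene = "character"))

setValidity("RegionalExpression", function(object) {
  msg <- character()
  if (nrow(object@density) != length(object@gene))
    msg <- c(msg, "one gene symbol per experiment row required")
  if (is.null(colnames(object@density)))
    msg <- c(msg, "density must have region colnames")
  if (any(is.na(object@density)) || any(object@density < 0))
    msg <- c(msg, "densities must be non-negative and complete")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionalExpression object
#'
#' @param density experiment x region matrix of expression densities
#'   (percentage of pixels).
#' @param gene gene symbol for each experiment row.
#' @return A validated [RegionalExpression-class].
#' @export
RegionalExpression <- function(density, gene) {
  density <- as.matrix(density)
  if (is.null(rownames(density)))
    rownames(density) <- paste0("exp", seq_len(nrow(density)))
  obj <- new("RegionalExpression", density = density,
             gene = as.character(gene))
  validObject(obj)
  obj
}

#' @describeIn RegionalExpression-class gene symbol of each experiment row.
#' @param x,object a `RegionalExpression`.
#' @export
expressionGenes <- function(x) x@gene

#' @describeIn RegionalExpression-class the density matrix.
#' @export
expressionDensity <- function(x) x@density

setMethod("show", "RegionalExpression", function(object) {
  cat("RegionalExpression: ", length(unique(object@gene)), " genes, ",
      nrow(object@density), " experiments, ",
      ncol(object@density), " regions\n", sep = "")
})
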