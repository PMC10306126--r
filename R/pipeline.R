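## Stage orchestration: each cmd* function runs one pipeline stage end to
## end, writes its artifacts into an output directory, and records a
## manifest (inputs, outputs with md5 checksums, effective config, seed,
## timestamp) so deterministic stages can be audited for byte-identical
## reruns. A thin shell entry point wrapping these lives at
## inst/scripts/fos-connectome.

.configAsList <- function(cfg) {
  list(correlationThreshold = cfg@correlationThreshold,
       linkageMethod = cfg@linkageMethod,
       cutFraction = cfg@cutFraction,
       hubTopK = cfg@hubTopK,
       fdrLevel = cfg@fdrLevel,
       excludedRegions = cfg@excludedRegions,
       rngSeed = cfg@rngSeed)
}

.writeManifest <- function(outDir, stage, inputs, outputs, config, seed) {
  manifest <- list(
    stage = stage,
    inputs = as.list(inputs),
    outputs = lapply(outputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    config = if (is(config, "RunConfig")) .configAsList(config) else config,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(outDir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a synthetic dataset with ground truth
#'
#' Generates a block-correlated count table (and optionally an expression
#' matrix against its realised LFC vector), writes counts, group map,
#' expression, ground truth (JSON) and a stage manifest with output
#' checksums. Deterministic given the spec seeds.
#'
#' @param countSpec a [syntheticCountSpec()].
#' @param outDir output directory (created if needed).
#' @param exprSpec optional [syntheticExpressionSpec()].
#' @return invisibly, the list of written paths.
#' @export
cmdSimulate <- function(countSpec, outDir, exprSpec = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- generateCounts(countSpec)
  fe <- sim$experiment
  countsPath <- file.path(outDir, "counts.csv")
  utils::write.csv(data.frame(region_id = regionIds(fe), fosCounts(fe),
                              check.names = FALSE),
                   countsPath, row.names = FALSE)
  groupPath <- file.path(outDir, "groups.csv")
  utils::write.csv(data.frame(subject = subjectIds(fe),
                              group = unname(subjectGroups(fe))),
                   groupPath, row.names = FALSE)
  truth <- list(moduleOfRegion = as.list(sim$truth$moduleOfRegion))
  outputs <- c(countsPath, groupPath)
  if (!is.null(exprSpec)) {
    lfc <- fosLfc(fe)
    ex <- generateExpression(exprSpec, lfc)
    exprPath <- file.path(outDir, "expression.csv")
    utils::write.csv(data.frame(gene = ex$expression@gene,
                                experiment = rownames(ex$expression@density),
                                ex$expression@density, check.names = FALSE),
                     exprPath, row.names = FALSE)
    truth$signalGeneIds <- ex$truth$signalGeneIds
    truth$realizedRho <- as.list(ex$truth$realizedRho)
    outputs <- c(outputs, exprPath)
  }
  truthPath <- file.path(outDir, "truth.json")
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, truthPath)
  .writeManifest(outDir, "simulate", character(), outputs,
                 config = unclass(countSpec), seed = countSpec$seed)
  invisible(outputs)
}

.readExpressionCsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  gene <- as.character(df$gene)
  expId <- if ("experiment" %in% names(df)) as.character(df$experiment)
  else paste0(gene, "_e1")
  dens <- as.matrix(df[, setdiff(names(df), c("gene", "experiment")),
                       drop = FALSE])
  rownames(dens) <- expId
  RegionalExpression(dens, gene)
}

#' Run the connectome stage end to end
#'
#' Reads (or accepts) a count table, then per group: correlation matrix,
#' half-height module partition, thresholded network with centralities and
#' hub flags — all written to `outDir` along with a summary JSON
#' (regions, edges, modules, hub sets per group) and a manifest.
#'
#' @param counts a [FosExperiment-class], or a count-table path.
#' @param outDir output directory.
#' @param groupMap group mapping (required when `counts` is a path; see
#'   [readCountTable()]).
#' @param config a [RunConfig-class].
#' @return invisibly, the summary list.
#' @export
cmdConnectome <- function(counts, outDir, groupMap = NULL,
                          config = runConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fe <- if (is(counts, "FosExperiment")) counts
  else readCountTable(counts, groupMap)
  fe <- normalizeCounts(fe)
  summary <- list(n_regions = nrow(fe), groups = list())
  outputs <- character()
  for (grp in c("control", "treatment")) {
    corr <- correlationMatrix(fe, grp)
    part <- clusterModules(corr, config)
    net <- thresholdGraph(corr, config)
    cent <- centralityTable(net, part, config)
    hubs <- identifyHubs(cent, config)

    corrPath <- file.path(outDir, paste0(grp, "_correlation.csv"))
    utils::write.csv(data.frame(region_id = rownames(corr@r), corr@r,
                                check.names = FALSE),
                     corrPath, row.names = FALSE)
    partPath <- file.path(outDir, paste0(grp, "_modules.csv"))
    utils::write.csv(data.frame(region_id = names(moduleAssignments(part)),
                                module = unname(moduleAssignments(part))),
                     partPath, row.names = FALSE)
    centPath <- file.path(outDir, paste0(grp, "_centrality.csv"))
    utils::write.csv(cent, centPath, row.names = FALSE)
    g <- net@graph
    idx <- match(igraph::V(g)$name, cent$region)
    igraph::V(g)$module <- cent$module[idx]
    igraph::V(g)$degree <- cent$degree[idx]
    igraph::V(g)$betweenness <- cent$betweenness[idx]
    igraph::V(g)$participation <- cent$participation[idx]
    igraph::V(g)$within_module_z <- cent$within_module_z[idx]
    igraph::V(g)$is_hub_deg_btw <- cent$is_hub_deg_btw[idx]
    igraph::V(g)$is_connector_hub <- cent$is_connector_hub[idx]
    netAnn <- new("ThresholdedNetwork", graph = g,
                  threshold = net@threshold)
    netPaths <- writeNetwork(netAnn, file.path(outDir, paste0(grp, "_network")))
    outputs <- c(outputs, corrPath, partPath, centPath, unname(netPaths))
    summary$groups[[grp]] <- list(
      n_regions = nrow(corr@r),
      dropped_regions = corr@dropped,
      n_edges = edgeCount(net),
      n_modules = nModules(part),
      hubs = hubs$hubs,
      connector_hubs = hubs$connectorHubs,
      mean_degree = mean(cent$degree),
      mean_participation = mean(cent$participation))
  }
  sumPath <- file.path(outDir, "connectome_summary.json")
  jsonlite::write_json(summary, sumPath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  outputs <- c(outputs, sumPath)
  .writeManifest(outDir, "connectome",
                 if (is.character(counts)) counts else "<in-memory>",
                 outputs, config, config@rngSeed)
  invisible(summary)
}

#' Run the gene-screen stage end to end
#'
#' Reads (or accepts) expression and count data, runs [runScreen()], and
#' writes the screen table (sorted by |r|), the significant-gene list
#' (one symbol per line, ready for pathway-tool upload), a summary JSON
#' including the realised |r| frontier, and a manifest.
#'
#' @param expr a [RegionalExpression-class] or a long/wide expression CSV
#'   path (columns `gene`, optional `experiment`, then regions).
#' @param counts a [FosExperiment-class] or count-table path.
#' @param outDir output directory.
#' @param groupMap group mapping when `counts` is a path.
#' @param config a [RunConfig-class].
#' @return invisibly, the screen data.frame.
#' @export
cmdGeneScreen <- function(expr, counts, outDir, groupMap = NULL,
                          config = runConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(expr)) {
    if (!file.exists(expr)) stop("expression file not found: ", expr)
    expr <- .readExpressionCsv(expr)
  }
  fe <- if (is(counts, "FosExperiment")) counts
  else readCountTable(counts, groupMap)
  res <- runScreen(expr, fe, config)
  screenPath <- file.path(outDir, "gene_screen.csv")
  utils::write.csv(res, screenPath, row.names = FALSE)
  listPath <- file.path(outDir, "significant_genes.txt")
  writeLines(res$gene[res$significant], listPath)
  summary <- list(n_genes_tested = sum(!is.na(res$p)),
                  n_significant = sum(res$significant),
                  fdr_level = config@fdrLevel,
                  r_frontier = attr(res, "frontier"),
                  n_regions_used = res$n_regions_used[1L])
  sumPath <- file.path(outDir, "screen_summary.json")
  jsonlite::write_json(summary, sumPath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  .writeManifest(outDir, "gene_screen", character(),
                 c(screenPath, listPath, sumPath), config, config@rngSeed)
  invisible(res)
}
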