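## Tabular and graph I/O. Count tables and metadata are delimited text
## (CSV/TSV autodetected by extension); networks go out as an edge-list CSV
## plus GraphML with node attributes.

.delimFor <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%OS1"),
                  stage, paste0(...)))
}

#' Read a regional Fos count table
#'
#' Reads a delimited file (CSV or TSV by extension) whose first column (or a
#' column named `region_id`/`region`) holds region acronyms and whose
#' remaining columns are per-subject Fos cell counts. Validation is
#' fail-fast: duplicate region ids, negative or non-numeric counts, and
#' subjects without a group label all raise before any computation. Rows
#' whose counts are all missing are dropped with a warning; any other
#' missing value is an error (the upstream cell-counting pipeline emits
#' complete tables, and imputation would silently change correlations).
#'
#' @param path file path.
#' @param groupMap named character vector mapping subject id to
#'   `"control"`/`"treatment"`, a two-column data.frame (`subject`,
#'   `group`), or the path of such a two-column delimited file.
#' @param regionData optional region metadata (see [readRegionMetadata()]).
#' @return A [FosExperiment-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(region_id = c("MS", "NDB"), s1 = 1:2, s2 = 3:4),
#'           tf, row.names = FALSE)
#' fe <- readCountTable(tf, c(s1 = "control", s2 = "control"))
#' @export
readCountTable <- function(path, groupMap, regionData = NULL) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  idCol <- intersect(c("region_id", "region", "acronym"), names(df))
  idCol <- if (length(idCol)) idCol[1L] else names(df)[1L]
  regions <- as.character(df[[idCol]])
  if (anyDuplicated(regions))
    stop("duplicate region id(s): ",
         paste(unique(regions[duplicated(regions)]), collapse = ", "))
  cts <- df[, setdiff(names(df), idCol), drop = FALSE]
  if (ncol(cts) < 1L) stop("no subject columns found")
  for (j in names(cts)) {
    v <- cts[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric count in column '", j, "'",
           if (length(bad)) paste0(", row(s) ",
                                   paste(regions[bad], collapse = ", ")))
    }
    neg <- which(!is.na(v) & v < 0)
    if (length(neg))
      stop("negative count in column '", j, "', row(s) ",
           paste(regions[neg], collapse = ", "))
  }
  m <- as.matrix(cts)
  rownames(m) <- regions
  allNA <- rowSums(!is.na(m)) == 0L
  if (any(allNA)) {
    warning("dropping region(s) with all-missing counts: ",
            paste(regions[allNA], collapse = ", "), call. = FALSE)
    m <- m[!allNA, , drop = FALSE]
  }
  if (any(is.na(m)))
    stop("missing counts are not allowed (partial-NA rows)")

  if (is.character(groupMap) && length(groupMap) == 1L &&
      is.null(names(groupMap)) && file.exists(groupMap))
    groupMap <- utils::read.table(groupMap, header = TRUE,
                                  sep = .delimFor(groupMap),
                                  stringsAsFactors = FALSE)
  if (is.data.frame(groupMap)) {
    gm <- as.character(groupMap[[2L]])
    names(gm) <- as.character(groupMap[[1L]])
    groupMap <- gm
  }
  .stageLog("io", "read ", nrow(m), " regions x ", ncol(m),
            " subjects from ", basename(path))
  FosExperiment(m, group = groupMap, regionData = regionData)
}

.anatomicGroups <- c("cortical plate", "cortical subplate", "striatum",
                     "pallidum", "thalamus", "hypothalamus", "midbrain",
                     "hindbrain", "cerebellum")

.cholinergicLabels <- c("Ch1(MS)", "Ch2/3(NDB)", "Ch4(MA)", "Ch4(SI)",
                        "Ch5(PPN)", "Ch7(MH)", "LH")

## Default split of the long-range cholinergic regions into the two
## subsystems used throughout: basal forebrain vs brainstem-thalamic.
.defaultSubsystems <- list(
  basal_forebrain = c("MA", "NDB", "SI"),
  brainstem_thalamic = c("MS", "PPN", "MH", "LH"))

#' Read region metadata
#'
#' Reads a delimited file with columns `region_id`, (optional) `name`,
#' `anatomic_group`, and optional `cholinergic_group` and `subsystem`.
#' `anatomic_group` is checked against the closed nine-value vocabulary
#' (cortical plate, cortical subplate, striatum, pallidum, thalamus,
#' hypothalamus, midbrain, hindbrain, cerebellum). When a cholinergic label
#' is present but `subsystem` is empty, the default split is applied:
#' basal forebrain = MA, NDB, SI; brainstem-thalamic = MS, PPN, MH, LH.
#'
#' @param path file path.
#' @return data.frame with one row per region; attribute
#'   `"cholinergicSets"` carries the two subsystem region sets.
#' @export
readRegionMetadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delimFor(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  req <- c("region_id", "anatomic_group")
  if (!all(req %in% names(df)))
    stop("metadata must contain columns: ", paste(req, collapse = ", "))
  df$region_id <- trimws(as.character(df$region_id))
  df$anatomic_group <- trimws(as.character(df$anatomic_group))
  if (anyDuplicated(df$region_id))
    stop("duplicate region id(s) in metadata")
  bad <- setdiff(stats::na.omit(unique(df$anatomic_group)), .anatomicGroups)
  if (length(bad))
    stop("unknown anatomic_group value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.anatomicGroups, collapse = ", "))
  if (!"cholinergic_group" %in% names(df)) df$cholinergic_group <- NA_character_
  if (!"subsystem" %in% names(df)) df$subsystem <- NA_character_
  df$cholinergic_group <- trimws(as.character(df$cholinergic_group))
  df$subsystem <- trimws(as.character(df$subsystem))
  if (any(!is.na(df$subsystem) & is.na(df$cholinergic_group)))
    stop("subsystem set for region(s) without a cholinergic_group")
  chol <- !is.na(df$cholinergic_group)
  fill <- chol & is.na(df$subsystem)
  if (any(fill)) {
    df$subsystem[fill] <- ifelse(
      df$region_id[fill] %in% .defaultSubsystems$basal_forebrain,
      "basal_forebrain",
      ifelse(df$region_id[fill] %in% .defaultSubsystems$brainstem_thalamic,
             "brainstem_thalamic", NA_character_))
  }
  sets <- list(
    basal_forebrain = df$region_id[!is.na(df$subsystem) &
                                     df$subsystem == "basal_forebrain"],
    brainstem_thalamic = df$region_id[!is.na(df$subsystem) &
                                        df$subsystem == "brainstem_thalamic"])
  if (!any(chol))
    warning("metadata contains no cholinergic regions; ",
            "subsystem analyses disabled", call. = FALSE)
  attr(df, "cholinergicSets") <- sets
  df
}

#' The default cholinergic subsystem sets
#'
#' Long-range cholinergic regions split into the basal forebrain system
#' (MA, NDB, SI) and the brainstem-thalamic system (MS, PPN, MH, LH). If
#' region metadata is supplied, the sets recorded there are returned
#' instead.
#'
#' @param meta optional metadata data.frame from [readRegionMetadata()].
#' @return list with elements `basal_forebrain` and `brainstem_thalamic`.
#' @export
cholinergicSets <- function(meta = NULL) {
  if (!is.null(meta)) {
    sets <- attr(meta, "cholinergicSets")
    if (!is.null(sets)) return(sets)
  }
  .defaultSubsystems
}

#' Write / read a thresholded network
#'
#' `writeNetwork()` writes both an edge-list CSV (`<prefix>_edges.csv` with
#' columns region_a, region_b, r) and a GraphML file (`<prefix>.graphml`)
#' carrying any node attributes attached to the graph (module, degree,
#' betweenness, participation, within-module z, hub flags).
#' `readNetwork()` re-reads the GraphML; the round trip reproduces nodes,
#' edges and attributes exactly.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param prefix output path prefix (directory must exist).
#' @return `writeNetwork()` invisibly returns the two paths;
#'   `readNetwork()` returns a [ThresholdedNetwork-class].
#' @export
writeNetwork <- function(net, prefix) {
  stopifnot(is(net, "ThresholdedNetwork"))
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  g <- net@graph
  el <- igraph::as_edgelist(g)
  r <- if ("r" %in% igraph::edge_attr_names(g))
    igraph::E(g)$r else rep(NA_real_, nrow(el))
  edgeDf <- data.frame(region_a = el[, 1L], region_b = el[, 2L], r = r,
                       stringsAsFactors = FALSE)
  edgePath <- paste0(prefix, "_edges.csv")
  utils::write.csv(edgeDf, edgePath, row.names = FALSE)
  gmlPath <- paste0(prefix, ".graphml")
  ig <- g
  igraph::graph_attr(ig, "threshold") <- net@threshold
  igraph::write_graph(ig, gmlPath, format = "graphml")
  invisible(c(edges = edgePath, graphml = gmlPath))
}

#' @rdname writeNetwork
#' @param path a GraphML file written by `writeNetwork()`.
#' @export
readNetwork <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  thr <- igraph::graph_attr(g, "threshold")
  if (is.null(thr)) thr <- NA_real_
  if (!is.null(igraph::vertex_attr(g, "id")))
    g <- igraph::delete_vertex_attr(g, "id")
  new("ThresholdedNetwork", graph = g, threshold = as.numeric(thr))
}

#' Read a run configuration from YAML or JSON
#'
#' Keys mirror the arguments of [runConfig()]; missing keys keep their
#' defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, vals)
}
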