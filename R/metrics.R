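## Graph-theoretic analysis of the thresholded functional network: degree,
## betweenness, participation coefficient, within-module degree z-score,
## dual-criterion hub identification, and Mann-Whitney comparisons of
## centrality distributions between networks.

#' Threshold a correlation matrix into a binary functional network
#'
#' An edge connects two regions iff their Pearson correlation is strictly
#' above the threshold. The resulting graph is undirected and unweighted
#' (the original r is kept as an edge attribute for export only).
#'
#' @param corr a [CorrelationMatrix-class].
#' @param config a [RunConfig-class] (its `correlationThreshold` is used),
#'   or a single number.
#' @return A [ThresholdedNetwork-class].
#' @export
thresholdGraph <- function(corr, config = runConfig()) {
  stopifnot(is(corr, "CorrelationMatrix"))
  thr <- if (is(config, "RunConfig")) config@correlationThreshold
  else as.numeric(config)
  r <- corr@r
  adj <- (r > thr)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    igraph::E(g)$r <- r[cbind(el[, 1L], el[, 2L])]
  }
  net <- new("ThresholdedNetwork", graph = g, threshold = thr)
  .stageLog("network", corr@group, ": ", igraph::ecount(g), " edges at r > ",
            thr)
  net
}

#' Node degree
#'
#' Number of functional connections (edges) incident to each region.
#'
#' @param net a [ThresholdedNetwork-class].
#' @return named integer vector.
#' @export
degreeCentrality <- function(net) {
  stopifnot(is(net, "ThresholdedNetwork"))
  d <- igraph::degree(net@graph, loops = FALSE)
  stats::setNames(as.integer(d), names(d))
}

#' Shortest-path betweenness
#'
#' For each region, the sum over unordered region pairs of the fraction of
#' geodesics passing through it; disconnected pairs contribute 0. Raw
#' (unnormalised) scores — hub calls depend only on ranks.
#'
#' @param net a [ThresholdedNetwork-class].
#' @return named numeric vector.
#' @export
betweennessCentrality <- function(net) {
  stopifnot(is(net, "ThresholdedNetwork"))
  igraph::betweenness(net@graph, directed = FALSE, weights = NA,
                      normalized = FALSE)
}

.moduleOf <- function(net, partition) {
  regions <- networkRegions(net)
  mods <- moduleAssignments(partition)
  missing <- setdiff(regions, names(mods))
  if (length(missing))
    stop("region(s) missing from the module partition: ",
         paste(missing, collapse = ", "))
  mods[regions]
}

#' Participation coefficient
#'
#' Guimera-Amaral participation: P_i = 1 - sum_s (k_is / k_i)^2, where k_is
#' counts i's edges into module s and k_i is i's degree. P is 0 when all of
#' a region's edges stay inside its own module (and for isolated regions),
#' and approaches 1 - 1/m when edges are spread evenly over m modules.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param partition a [ModulePartition-class] covering all network nodes.
#' @return named numeric vector in [0, 1].
#' @export
participationCoef <- function(net, partition) {
  mods <- .moduleOf(net, partition)
  g <- net@graph
  regions <- networkRegions(net)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  ## k_is: edges from each node into each module
  modFac <- factor(mods)
  kis <- t(rowsum(t(adj), group = modFac))   # nodes x modules
  p <- ifelse(k > 0, 1 - rowSums((kis / pmax(k, 1))^2), 0)
  stats::setNames(as.numeric(p), regions)
}

#' Within-module degree z-score
#'
#' Standardises each region's within-module degree against the mean and
#' population (n-divisor) standard deviation of within-module degrees in
#' its own module; modules whose within-degrees are all equal (including
#' singletons) get z = 0.
#'
#' @inheritParams participationCoef
#' @return named numeric vector.
#' @export
withinModuleZ <- function(net, partition) {
  mods <- .moduleOf(net, partition)
  adj <- igraph::as_adjacency_matrix(net@graph, sparse = FALSE)
  regions <- networkRegions(net)
  z <- stats::setNames(numeric(length(regions)), regions)
  for (s in unique(mods)) {
    members <- regions[mods == s]
    kappa <- rowSums(adj[members, members, drop = FALSE])
    mu <- mean(kappa)
    sdPop <- sqrt(mean((kappa - mu)^2))
    z[members] <- if (sdPop > 0) (kappa - mu) / sdPop else 0
  }
  z
}

.topK <- function(x, k) {
  ## top-k with ties: everything tied with the k-th value is included
  if (length(x) <= k) return(names(x))
  cut <- sort(x, decreasing = TRUE)[k]
  names(x)[x >= cut]
}

#' Per-region centrality table with hub flags
#'
#' Combines degree, betweenness, participation coefficient, within-module
#' z-score and module membership, and flags the two hub classes defined by
#' [identifyHubs()].
#'
#' @param net a [ThresholdedNetwork-class].
#' @param partition a [ModulePartition-class].
#' @param config a [RunConfig-class] (its `hubTopK` is used).
#' @return data.frame with one row per region.
#' @export
centralityTable <- function(net, partition, config = runConfig()) {
  deg <- degreeCentrality(net)
  btw <- betweennessCentrality(net)
  part <- participationCoef(net, partition)
  z <- withinModuleZ(net, partition)
  mods <- .moduleOf(net, partition)
  tab <- data.frame(region = networkRegions(net), module = as.integer(mods),
                    degree = deg, betweenness = btw, participation = part,
                    within_module_z = z, row.names = NULL,
                    stringsAsFactors = FALSE)
  hubs <- identifyHubs(tab, config)
  tab$is_hub_deg_btw <- tab$region %in% hubs$hubs
  tab$is_connector_hub <- tab$region %in% hubs$connectorHubs
  tab
}

#' Identify hub regions
#'
#' Two hub classes: (A) regions in both the top-k degree and top-k
#' betweenness lists (the dual criterion); (B) "connector hubs", the top-k
#' participation-coefficient regions, whose edges spread across modules.
#' Regions tied with the k-th value are included, so lists may exceed k.
#'
#' @param cent a centrality data.frame with columns `region`, `degree`,
#'   `betweenness`, `participation` (as built by [centralityTable()]).
#' @param config a [RunConfig-class]; `hubTopK` sets k.
#' @return list with character vectors `hubs` (class A) and
#'   `connectorHubs` (class B).
#' @export
identifyHubs <- function(cent, config = runConfig()) {
  k <- if (is(config, "RunConfig")) config@hubTopK else as.integer(config)
  deg <- stats::setNames(cent$degree, cent$region)
  btw <- stats::setNames(cent$betweenness, cent$region)
  part <- stats::setNames(cent$participation, cent$region)
  hubs <- intersect(.topK(deg, k), .topK(btw, k))
  list(hubs = hubs, connectorHubs = .topK(part, k))
}

#' Mann-Whitney U comparison of two centrality distributions
#'
#' Two-sided rank-sum test (tie-corrected); the exact null distribution is
#' used for small tie-free samples and the normal approximation otherwise,
#' as in [stats::wilcox.test()]. The reported U is the statistic for the
#' first sample.
#'
#' @param a,b numeric vectors of per-region centrality values.
#' @return list with elements `U` and `p`.
#' @export
compareCentrality <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}
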