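## Independent brute-force oracles and small fixture builders. These stay
## deliberately naive (loops, enumeration) so they share no code path with
## the implementation they check.

## Pearson r from first principles
brutePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## Euclidean row-distance matrix by explicit loops
bruteRowDistance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (k in seq_len(ncol(m))) s <- s + (m[i, k] - m[j, k])^2
    d[i, j] <- sqrt(s)
  }
  d
}

## BFS shortest-path distances and geodesic counts from one source
.bfsCount <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n); sigma <- numeric(n)
  dist[s] <- 0; sigma[s] <- 1
  cur <- s; d <- 0
  while (length(cur)) {
    cand <- which(is.infinite(dist))
    if (!length(cand)) break
    reach <- cand[colSums(adj[cur, cand, drop = FALSE]) > 0]
    for (w in reach) sigma[w] <- sum(sigma[cur] * adj[cur, w])
    dist[reach] <- d + 1
    cur <- reach; d <- d + 1
  }
  list(dist = dist, sigma = sigma)
}

## Betweenness by all-pairs geodesic enumeration: for every unordered pair
## (s,t) and interior node v, add sigma_sv * sigma_vt / sigma_st when v
## lies on a geodesic. Independent of Brandes-style accumulation.
bruteBetweenness <- function(adj) {
  n <- nrow(adj)
  bfs <- lapply(seq_len(n), function(s) .bfsCount(adj, s))
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    dst <- bfs[[s]]$dist[t]
    if (is.infinite(dst)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (bfs[[s]]$dist[v] + bfs[[v]]$dist[t] == dst)
        btw[v] <- btw[v] +
          bfs[[s]]$sigma[v] * bfs[[v]]$sigma[t] / bfs[[s]]$sigma[t]
    }
  }
  btw
}

## Participation coefficient by direct double loop over nodes and modules
bruteParticipation <- function(adj, mods) {
  n <- nrow(adj)
  p <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(adj[i, ])
    if (k == 0) next
    acc <- 0
    for (s in unique(mods)) {
      kis <- sum(adj[i, mods == s])
      acc <- acc + (kis / k)^2
    }
    p[i] <- 1 - acc
  }
  p
}

## Benjamini-Hochberg by literal step-up enumeration: find the largest j
## with p_(j) <= j*alpha/m, reject p_(1..j); q_i = min_{j >= rank(i)} m*p_(j)/j
bruteBH <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  jmax <- 0
  for (j in seq_len(m)) if (ps[j] <= j * alpha / m) jmax <- j
  reject <- logical(m)
  if (jmax > 0) reject[o[seq_len(jmax)]] <- TRUE
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(m * ps[rank_i:m] / (rank_i:m)))
  }
  list(q = q, reject = reject)
}

## Balanced two-way ANOVA from the textbook sums-of-squares decomposition
bruteAnovaBalanced <- function(y, fa, fb) {
  fa <- factor(fa); fb <- factor(fb)
  n <- length(y)
  a <- nlevels(fa); b <- nlevels(fb)
  nc <- n / (a * b)                        # per-cell count (balanced)
  gm <- mean(y)
  ma <- tapply(y, fa, mean); mb <- tapply(y, fb, mean)
  mab <- tapply(y, interaction(fa, fb), mean)
  ssa <- b * nc * sum((ma - gm)^2)
  ssb <- a * nc * sum((mb - gm)^2)
  sstot <- sum((y - gm)^2)
  ssab <- nc * sum((mab - gm)^2) - ssa - ssb
  sse <- sstot - ssa - ssb - ssab
  dfe <- n - a * b
  list(Fa = (ssa / (a - 1)) / (sse / dfe),
       Fb = (ssb / (b - 1)) / (sse / dfe),
       Fab = (ssab / ((a - 1) * (b - 1))) / (sse / dfe),
       dfe = dfe)
}

## Exact two-sided Mann-Whitney p by enumerating every assignment of the
## pooled observations to the two groups (tie-free samples only)
bruteMannWhitneyP <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  rk <- rank(pooled)
  uObs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2)
  pLe <- mean(us <= uObs)
  pGe <- mean(us >= uObs)
  min(1, 2 * min(pLe, pGe))
}

## ---- fixture builders ------------------------------------------------------

## random symmetric 0/1 adjacency with empty diagonal
randomAdjacency <- function(n, pEdge = 0.3) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(stats::runif(sum(up)) < pEdge)
  adj + t(adj)
}

## ThresholdedNetwork straight from an adjacency matrix
netFromAdjacency <- function(adj, threshold = 0.75) {
  n <- nrow(adj)
  dimnames(adj) <- list(sprintf("R%02d", 1:n), sprintf("R%02d", 1:n))
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  new("ThresholdedNetwork", graph = g, threshold = threshold)
}

## ModulePartition from a plain assignment vector
partitionFromVector <- function(mods, regions = NULL) {
  if (is.null(regions)) regions <- sprintf("R%02d", seq_along(mods))
  m <- stats::setNames(as.integer(mods), regions)
  new("ModulePartition", modules = m,
      nModules = length(unique(m)), cutHeight = 0, tree = NULL)
}

## CorrelationMatrix with specified off-diagonal entries
corrFromMatrix <- function(r, group = "control", regions = NULL) {
  if (is.null(regions)) regions <- sprintf("R%02d", seq_len(nrow(r)))
  dimnames(r) <- list(regions, regions)
  diag(r) <- 1
  new("CorrelationMatrix", r = r, group = group, dropped = character())
}

## FosExperiment whose log10(count+1) values equal `values` exactly is not
## generally constructible from integer counts, so tests that need exact
## normalised values inject them into the lognorm assay.
feFromCounts <- function(counts, group) {
  suppressWarnings(FosExperiment(counts, group = group))
}

feWithLogValues <- function(values, group) {
  cts <- matrix(0L, nrow(values), ncol(values), dimnames = dimnames(values))
  fe <- suppressWarnings(FosExperiment(cts, group = group))
  SummarizedExperiment::assay(fe, "lognorm") <- values
  fe
}

## Path of the study Fos count table, if a user has converted and dropped
## it in; NULL when absent (it is not redistributable with the package).
studyCountsPath <- function() {
  p <- system.file("extdata", "study_fos_counts.tsv",
                   package = "FosConnectome")
  if (nzchar(p) && file.exists(p)) p else NULL
}
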