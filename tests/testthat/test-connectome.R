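test_that("log normalisation maps counts to log10(x+1) exactly", {
  m <- matrix(c(0L, 99L, 999L, 9L, 0L, 1L), 3, 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  m <- cbind(m, m + 1L); colnames(m) <- paste0("s", 1:4)
  fe <- feFromCounts(m, rep(c("control", "treatment"), each = 2))
  ln <- logCounts(fe)
  expect_identical(dim(ln), dim(m))
  expect_equal(ln["A", "s1"], 0)          # log10(0+1)
  expect_equal(ln["B", "s1"], 2)          # log10(99+1)
  expect_equal(ln["C", "s1"], 3)          # log10(999+1)
  expect_true(all((ln == 0) == (m == 0))) # zero iff count zero
  expect_true(all(ln >= 0))
})

test_that("within-group Pearson correlation matches hand cases and a brute-force oracle", {
  # crafted counts whose log10(x+1) values are (1,2,3) / (2,4,6) / (3,2,1)
  cts <- rbind(A = c(9L, 99L, 999L),
               B = c(99L, 9999L, 999999L),
               C = c(999L, 99L, 9L))
  colnames(cts) <- paste0("s", 1:3)
  cts <- cbind(cts, t1 = c(1L, 1L, 2L), t2 = c(2L, 2L, 1L))
  fe <- feFromCounts(cts, c(rep("control", 3), rep("treatment", 2)))
  r <- corValues(correlationMatrix(fe, "control"))
  expect_equal(diag(r), c(A = 1, B = 1, C = 1))
  expect_equal(r["A", "B"], 1)            # perfect linearity
  expect_equal(r["A", "C"], -1)           # perfect anticorrelation

  # random table vs independent covariance/sigma-sigma oracle
  set.seed(101)
  m <- matrix(rpois(50, 80), 10, 5,
              dimnames = list(sprintf("R%02d", 1:10), sprintf("s%d", 1:5)))
  m <- cbind(m, matrix(rpois(20, 80), 10, 2,
                       dimnames = list(NULL, c("t1", "t2"))))
  fe <- feFromCounts(m, c(rep("control", 5), rep("treatment", 2)))
  r <- corValues(correlationMatrix(fe, "control"))
  ln <- log10(m[, 1:5] + 1)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(r[i, j], brutePearson(ln[i, ], ln[j, ]), tolerance = 1e-12)
})

test_that("zero-variance regions are excluded and degenerate groups error", {
  m <- rbind(A = c(5L, 5L, 5L, 1L, 9L), B = c(1L, 4L, 9L, 2L, 3L),
             C = c(2L, 6L, 4L, 7L, 8L))
  colnames(m) <- paste0("s", 1:5)
  fe <- feFromCounts(m, c(rep("control", 3), rep("treatment", 2)))
  expect_warning(corr <- correlationMatrix(fe, "control"),
                 "zero-variance.*A")
  expect_equal(rownames(corValues(corr)), c("B", "C"))
  expect_equal(corr@dropped, "A")

  flat <- matrix(3L, 3, 4, dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  feFlat <- feFromCounts(flat, rep(c("control", "treatment"), each = 2))
  expect_error(correlationMatrix(feFlat, "control"), "all regions")
})

test_that("correlation is invariant to per-region positive affine rescaling", {
  set.seed(7)
  v <- matrix(rnorm(40, 2, 0.5), 8, 5,
              dimnames = list(sprintf("R%02d", 1:8), sprintf("s%d", 1:5)))
  v2 <- v
  a <- runif(8, 0.5, 3); b <- runif(8, -1, 1)
  for (i in 1:8) v2[i, ] <- a[i] * v[i, ] + b[i]
  grp <- c(rep("control", 3), rep("treatment", 2))
  r1 <- corValues(correlationMatrix(feWithLogValues(v, grp), "control"))
  r2 <- corValues(correlationMatrix(feWithLogValues(v2, grp), "control"))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("functional distances are Euclidean norms of correlation rows", {
  # rows (1,0) and (0,1): distance sqrt(2)
  r <- matrix(0, 2, 2)
  corr <- corrFromMatrix(r)
  d <- as.matrix(correlationDistance(corr))
  expect_equal(d[1, 2], sqrt(2))
  expect_equal(diag(d), c(R01 = 0, R02 = 0))

  # identical rows -> 0 (two regions perfectly correlated with everything alike)
  r3 <- matrix(c(1, 1, .2, 1, 1, .2, .2, .2, 1), 3, 3)
  d3 <- as.matrix(correlationDistance(corrFromMatrix(r3)))
  expect_equal(d3[1, 2], 0)

  # random correlation-like matrix vs elementwise-loop oracle
  set.seed(21)
  x <- matrix(runif(36, -1, 1), 6, 6)
  x <- (x + t(x)) / 2
  corr <- corrFromMatrix(x)
  expect_equal(as.matrix(correlationDistance(corr)),
               bruteRowDistance(corValues(corr)),
               tolerance = 1e-12, ignore_attr = TRUE)
  # metric properties: symmetry and triangle inequality
  dm <- as.matrix(correlationDistance(corr))
  expect_equal(dm, t(dm))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
})

test_that("the half-height cut recovers planted blocks and handles degenerate input", {
  one <- stats::dist(matrix(0, 1, 1, dimnames = list("solo", NULL)))
  # dist of a single point has Size 1; construct via the matrix route
  part1 <- clusterModules(structure(numeric(0), Size = 1L, Labels = "solo",
                                    class = "dist"))
  expect_equal(nModules(part1), 1L)
  expect_equal(cutHeight(part1), 0)

  spec <- syntheticCountSpec(blockSizes = c(12, 12), withinR = 0.95,
                             betweenR = 0, nSubjectsPerGroup = 40, seed = 3)
  sim <- generateCounts(spec)
  corr <- correlationMatrix(sim$experiment, "control")
  part <- clusterModules(corr)
  expect_equal(nModules(part), 2L)
  mods <- moduleAssignments(part)
  truth <- sim$truth$moduleOfRegion[names(mods)]
  expect_equal(length(unique(paste(mods, truth))), 2L)  # exact match up to labels
  # half-height definition
  expect_equal(cutHeight(part), 0.5 * max(part@tree$height))
  # labels partition the regions: sizes sum to region count
  expect_equal(sum(table(mods)), nrow(corValues(corr)))
  # module ids follow dendrogram leaf order
  expect_equal(mods[part@tree$labels[part@tree$order[1]]], c(1L)[1],
               ignore_attr = TRUE)
})

test_that("lowering the cut fraction never decreases the module count", {
  set.seed(17)
  m <- matrix(rpois(20 * 8, 60), 20, 8,
              dimnames = list(sprintf("R%02d", 1:20), sprintf("s%d", 1:8)))
  fe <- feFromCounts(m, rep(c("control", "treatment"), each = 4))
  corr <- correlationMatrix(fe, "control")
  fracs <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  counts <- sapply(fracs, function(f)
    nModules(clusterModules(corr, runConfig(cutFraction = f))))
  expect_true(all(diff(counts) >= 0))
})
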