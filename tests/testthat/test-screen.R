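test_that("Fos log-fold change is the difference of group means on the log scale", {
  # identical group means -> 0
  m <- cbind(c1 = c(9L, 99L), c2 = c(9L, 99L),
             t1 = c(9L, 99L), t2 = c(9L, 99L))
  rownames(m) <- c("A", "B")
  fe <- feFromCounts(m, c("control", "control", "treatment", "treatment"))
  expect_equal(fosLfc(fe), c(A = 0, B = 0))

  # treatment counts ~10x control: LFC ~ 1 at large counts
  m10 <- cbind(c1 = c(1000L, 5000L), c2 = c(1000L, 5000L),
               t1 = c(10000L, 50000L), t2 = c(10000L, 50000L))
  rownames(m10) <- c("A", "B")
  fe10 <- feFromCounts(m10, c("control", "control", "treatment", "treatment"))
  expect_equal(unname(fosLfc(fe10)), c(1, 1), tolerance = 1e-3)

  # toy hand arithmetic
  mt <- cbind(c1 = c(9L, 0L), c2 = c(99L, 0L), t1 = c(999L, 9L), t2 = c(9L, 9L))
  rownames(mt) <- c("A", "B")
  fet <- feFromCounts(mt, c("control", "control", "treatment", "treatment"))
  expect_equal(fosLfc(fet),
               c(A = (3 + 1) / 2 - (1 + 2) / 2, B = 1 - 0))
  # exclusion bookkeeping
  expect_equal(names(fosLfc(fet, excludedRegions = "A")), "B")
})

test_that("per-experiment z-scoring then averaging is idempotent and affine-invariant", {
  v <- c(10, 20, 30, 40, 25)
  regions <- sprintf("R%02d", 1:5)
  one <- RegionalExpression(matrix(v, 1, 5, dimnames = list("e1", regions)),
                            gene = "g1")
  z1 <- aggregateExpression(one)
  expect_equal(unname(z1["g1", ]), as.numeric(scale(v)))

  two <- RegionalExpression(rbind(e1 = v, e2 = v) |>
                              `colnames<-`(regions), gene = c("g1", "g1"))
  expect_equal(aggregateExpression(two)["g1", ], z1["g1", ])

  aff <- RegionalExpression(rbind(e1 = v, e2 = 3 * v + 7) |>
                              `colnames<-`(regions), gene = c("g1", "g1"))
  expect_equal(aggregateExpression(aff)["g1", ], z1["g1", ],
               tolerance = 1e-12)

  # zero-variance experiment dropped; gene with none left excluded
  mix <- RegionalExpression(rbind(e1 = v, e2 = rep(5, 5)) |>
                              `colnames<-`(regions), gene = c("g1", "g2"))
  expect_warning(agg <- suppressMessages(aggregateExpression(mix)),
                 "zero-variance")
  expect_equal(rownames(agg), "g1")
})

test_that("gene correlation tests match the t-distribution and cor.test", {
  lfc <- setNames(c(0.1, 0.5, 0.2, 0.9, 0.4), sprintf("R%02d", 1:5))
  gm <- rbind(prop = 2 * lfc + 3)          # proportional to lfc
  colnames(gm) <- names(lfc)
  res <- correlateGenes(gm, lfc)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)

  # r = 0.23 at n = 174: p from t = r*sqrt((n-2)/(1-r^2))
  tval <- 0.23 * sqrt(172 / (1 - 0.23^2))
  pExpected <- 2 * pt(-tval, 172)
  expect_equal(pExpected, 2.3e-3, tolerance = 0.05)
  # build a vector with sample correlation exactly 0.23 against lfc174
  set.seed(111)
  lfc174 <- setNames(rnorm(174), sprintf("R%03d", 1:174))
  e <- rnorm(174)
  e <- residuals(lm(e ~ lfc174))           # orthogonal to lfc174
  zl <- as.numeric(scale(lfc174)); ze <- as.numeric(scale(e))
  g <- 0.23 * zl + sqrt(1 - 0.23^2) * ze
  gm2 <- matrix(g, 1, 174, dimnames = list("g", names(lfc174)))
  res2 <- correlateGenes(gm2, lfc174)
  expect_equal(res2$r, 0.23, tolerance = 1e-10)
  expect_equal(res2$p, pExpected, tolerance = 1e-10)

  # vectorised implementation agrees with cor.test (independent route)
  set.seed(112)
  gm3 <- matrix(rnorm(10 * 174), 10, 174,
                dimnames = list(paste0("g", 1:10), names(lfc174)))
  res3 <- correlateGenes(gm3, lfc174)
  for (i in 1:10) {
    ct <- cor.test(gm3[i, ], lfc174)
    expect_equal(res3$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res3$p[i], ct$p.value, tolerance = 1e-12)
  }

  # zero-variance gene untestable, error below 3 shared regions
  gm4 <- rbind(flat = rep(1, 174), ok = rnorm(174))
  colnames(gm4) <- names(lfc174)
  res4 <- correlateGenes(gm4, lfc174)
  expect_true(is.na(res4$p[res4$gene == "flat"]))
  expect_error(correlateGenes(gm2[, 1:2, drop = FALSE], lfc174[1:2]),
               "at least 3")
})

test_that("null p-values are uniform (KS calibration at n = 174)", {
  set.seed(113)
  lfc <- setNames(rnorm(174), sprintf("R%03d", 1:174))
  gm <- matrix(rnorm(1e4 * 174), 1e4, 174,
               dimnames = list(paste0("g", 1:1e4), names(lfc)))
  p <- correlateGenes(gm, lfc)$p
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH q-values match the brute-force step-up construction", {
  expect_equal(bhFdr(0.2)$q, 0.2)          # m = 1
  four <- bhFdr(c(0.01, 0.02, 0.03, 0.04), level = 0.05)
  expect_true(all(four$significant))       # p_(4)=0.04 <= 4*0.05/4
  set.seed(121)
  for (i in 1:30) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    got <- bhFdr(p, level = 0.05)
    oracle <- bruteBH(p, 0.05)
    expect_equal(got$q, oracle$q, tolerance = 1e-12)
    expect_equal(got$significant, oracle$reject)
    expect_true(all(got$q >= got$p))
    # q monotone non-decreasing in sorted p order
    expect_true(all(diff(got$q[order(p)]) >= -1e-12))
  }
  expect_equal(nrow(bhFdr(numeric(0))), 0L)
})

test_that("the composed screen behaves under the null and keeps region bookkeeping", {
  spec <- syntheticCountSpec(blockSizes = c(15, 15), withinR = 0.5,
                             betweenR = 0.1, globalRBoost = 0.2,
                             nSubjectsPerGroup = 5, seed = 7)
  fe <- generateCounts(spec)$experiment
  lfc <- fosLfc(fe)
  null <- generateExpression(
    syntheticExpressionSpec(nNullGenes = 400, nSignalGenes = 0, seed = 8), lfc)
  res <- suppressMessages(runScreen(null$expression, fe,
                                    runConfig(excludedRegions = character(0))))
  expect_lte(mean(res$significant), 0.05)  # null discovery share
  expect_true(all(diff(abs(res$r)) <= 1e-12))  # sorted by |r| descending
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  expect_true(all(res$significant == (res$q <= 0.05), na.rm = TRUE))
  expect_equal(res$n_regions_used[1], 30L)

  # excluding one configured region changes n_regions_used by exactly 1
  res2 <- suppressMessages(runScreen(null$expression, fe,
                                     runConfig(excludedRegions = "R001")))
  expect_equal(res2$n_regions_used[1], 29L)

  # screen invariant to gene ordering
  d <- expressionDensity(null$expression)
  perm <- sample(nrow(d))
  shuf <- RegionalExpression(d[perm, ], expressionGenes(null$expression)[perm])
  res3 <- suppressMessages(runScreen(shuf, fe,
                                     runConfig(excludedRegions = character(0))))
  expect_equal(res3[order(res3$gene), c("r", "p", "q")],
               res[order(res$gene), c("r", "p", "q")],
               ignore_attr = TRUE, tolerance = 1e-12)
})
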