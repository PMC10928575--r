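test_that("partial R2 hits its exact bounds", {
  set.seed(1)
  n <- 200
  X <- cbind(`(Intercept)` = 1, b1 = rnorm(n), b2 = rnorm(n), o1 = rnorm(n))
  yFull <- 2 * X[, "b1"] - X[, "b2"]               # exactly the block
  expect_equal(partialR2(yFull, X, c("b1", "b2")), 1, tolerance = 1e-12)
  yNull <- X[, "o1"]                               # orthogonal to the block
  expect_lt(partialR2(yNull, X, c("b1", "b2")), 1e-10)
})

test_that("partial R2 equals the two-model SSE oracle", {
  set.seed(2)
  n <- 500
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rnorm(n), c = rnorm(n),
             d = rnorm(n))
  y <- X %*% c(1, 0.5, -0.3, 0.2, 0) + rnorm(n)
  for (block in list("a", c("b", "c"), c("a", "d"))) {
    sseF <- sum(olsOracle(X, y)$residuals^2)
    sseR <- sum(olsOracle(X[, setdiff(colnames(X), block)], y)$residuals^2)
    expect_equal(partialR2(y, X, block), (sseR - sseF) / sseR,
                 tolerance = 1e-10)
  }
})

test_that("single-column partial R2 equals the squared partial correlation", {
  set.seed(3)
  n <- 300
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rnorm(n))
  y <- drop(X %*% c(1, 0.4, -0.7)) + rnorm(n)
  ## oracle: correlation of the two residual vectors
  rxy <- cor(olsOracle(X[, c(1, 3)], y)$residuals,
             olsOracle(X[, c(1, 3)], X[, "a"])$residuals)
  expect_equal(partialR2(y, X, "a"), rxy^2, tolerance = 1e-10)
})

test_that("additional R2 matches the analytic variance share", {
  set.seed(4)
  n <- 400
  base <- cbind(`(Intercept)` = 1, x = rnorm(n))
  zRaw <- rnorm(n)
  z <- olsOracle(base, zRaw)$residuals             # orthogonal to baseline
  y0 <- drop(base %*% c(1, 2))
  y <- y0 + 0.5 * z
  ## all y-variance beyond the baseline comes from z
  expect_equal(additionalR2(y, base, z),
               var(0.5 * z) * (n - 1) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  ## orthogonal cell adds nothing
  z2 <- olsOracle(cbind(base, z), rnorm(n))$residuals
  expect_lt(additionalR2(y, base, z2), 1e-10)
  ## never negative
  for (i in 1:5)
    expect_gte(additionalR2(rnorm(n), base, rnorm(n)), -1e-12)
  ## collinear addition warns and returns zero
  expect_warning(r0 <- additionalR2(y, base, base[, "x"]), "collinear")
  expect_equal(r0, 0)
})

test_that("composition PCA reconstructs and ranks variance", {
  ## rank-1 pattern: PC1 explains everything
  p2 <- rbind(matrix(rep(c(0.6, 0.4, rep(0, 10)), 5), 5, byrow = TRUE),
              matrix(rep(c(0.4, 0.6, rep(0, 10)), 5), 5, byrow = TRUE))
  colnames(p2) <- cellTypes12()
  md2 <- simulateSampleMetadata(10, seed = 5)
  pca2 <- pcaComposition(p2, md2)
  expect_gt(pca2$varExplained[1], 1 - 1e-12)
  ## reconstruction at full rank
  ch <- fixCohort()
  est <- estimateProportions(ch, fixRef())
  md <- sampleMetadata(ch)
  pca <- pcaComposition(est, md)
  Xc <- scale(proportions(est), center = TRUE, scale = FALSE)
  expect_lt(max(abs(Xc - pca$scores %*% t(pca$loadings))), 1e-8)
  expect_true(all(c("batch", "age") %in% pca$associations$covariate))
})

test_that("independent batches show no PC association", {
  hits <- 0L
  nSim <- 100
  for (s in seq_len(nSim)) {
    md <- simulateSampleMetadata(150, seed = 7000 + s)
    p <- sampleComposition(bloodCompositionModel(), md, seed = 7500 + s)
    pca <- pcaComposition(p, md)
    pBatch <- pca$associations$p[pca$associations$pc == 1 &
                                   pca$associations$covariate == "batch"]
    if (pBatch < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 10)   # non-significant in >= 90% of simulations
})

test_that("degenerate compositions are rejected", {
  p <- matrix(1 / 12, 5, 12, dimnames = list(NULL, cellTypes12()))
  md <- simulateSampleMetadata(5, seed = 1)
  expect_error(pcaComposition(p, md), "degenerate")
})

test_that("the decomposition wrapper returns both views", {
  ch <- fixCohort()
  est <- estimateProportions(ch, fixRef())
  md <- sampleMetadata(ch)
  ck <- generateClockPanel(fixRef(), fixDrift(), seed = 5)$mitoticClock
  ev <- computeMAge(ch, ck)
  d <- decomposeEaaVariance(eaaResidual(ev$mage, md$age), est, md)
  expect_named(d$partial, c("cells", "sex", "ancestry", "disease", "age"))
  expect_named(d$additional, cellTypes12())
  ok <- !is.na(d$partial)
  expect_true(all(d$partial[ok] >= 0 & d$partial[ok] <= 1))
  expect_true(all(d$additional >= 0))
})
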