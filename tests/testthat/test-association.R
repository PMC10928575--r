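test_that("age groups partition as specified", {
  age <- c(0, 0.5, 17.9, 18, 50, 99)
  g <- assignAgeGroups(age)
  expect_identical(g$newborn, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(g$pediatric, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(g$adult, !g$pediatric)
  expect_true(all(g$pediatric[g$newborn]))        # newborns are pediatric too
  expect_error(assignAgeGroups(c(-1)), "0, 99")
})

test_that("z-scores are exact within groups", {
  expect_equal(zscoreByGroup(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscoreByGroup(c(-1, 0, 1))
  expect_equal(zscoreByGroup(z), z, tolerance = 1e-12)    # idempotent
  set.seed(5)
  x <- c(rnorm(30, 100, 10), rnorm(20, 2, 0.1))
  gr <- rep(c("a", "b"), c(30, 20))
  z2 <- zscoreByGroup(x, gr)
  for (g in c("a", "b")) {
    expect_equal(z2[gr == g], zscoreOracle(x[gr == g]), tolerance = 1e-12)
    expect_lt(abs(mean(z2[gr == g])), 1e-12)
    expect_lt(abs(sd(z2[gr == g]) - 1), 1e-12)
  }
  expect_error(zscoreByGroup(c(1, 1, 1), rep("flat", 3)), "flat")
})

test_that("the per-cell model recovers a perfect association", {
  set.seed(7)
  md <- simulateSampleMetadata(200, seed = 7)
  z <- zscoreByGroup(rnorm(200))
  f <- fitCellModel(z, z, md)
  expect_equal(f$beta, 1, tolerance = 1e-8)
  expect_lt(f$p, 1e-100)
})

test_that("newborn-only fits drop age terms as constants", {
  md <- simulateSampleMetadata(80, seed = 8)
  md$age <- 0
  set.seed(8)
  f <- fitCellModel(zscoreByGroup(rnorm(80)), zscoreByGroup(rnorm(80)), md)
  dropped <- strsplit(f$dropped, ";")[[1]]
  expect_true(all(c("age", "age2") %in% dropped))
})

test_that("the mutually adjusted model is order-invariant and targeted", {
  set.seed(9)
  md <- simulateSampleMetadata(400, seed = 9)
  Z <- matrix(rnorm(400 * 12), 400, 12, dimnames = list(NULL, cellTypes12()))
  y <- 0.5 * Z[, "Treg"] + rnorm(400, 0, 0.5)
  yz <- zscoreByGroup(y)
  a <- fitMutuallyAdjustedModel(yz, Z, md)
  b <- fitMutuallyAdjustedModel(yz, Z[, rev(colnames(Z))], md)
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
  q <- bhFdr(a$p)$q
  expect_lt(q[a$cell == "Treg"], 0.05)
  expect_gt(min(a$p[a$cell != "Treg"]), 0.001)
})

test_that("per-cell null p-values are uniform (KS oracle)", {
  set.seed(10)
  md <- simulateSampleMetadata(250, seed = 10)
  ps <- replicate(300, {
    fitCellModel(zscoreByGroup(rnorm(250)), zscoreByGroup(rnorm(250)), md)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH step-up matches direct evaluation and brute force", {
  r <- bhFdr(c(0.01, 0.5))
  expect_equal(r$q, c(0.02, 0.5))
  expect_identical(r$reject, c(TRUE, FALSE))
  expect_true(all(bhFdr(rep(0, 5))$reject))
  expect_length(bhFdr(numeric(0))$q, 0)
  set.seed(11)
  for (i in 1:5) {
    p <- runif(20)^(1 + i / 3)
    q <- bhFdr(p)$q
    expect_true(all(q >= p - 1e-12))
    expect_lt(max(abs(q - bhBruteForce(p))), 1e-4 + 1e-12)
  }
})

test_that("BH controls the FDR in a null simulation", {
  set.seed(12)
  falseRej <- replicate(200, mean(bhFdr(runif(50))$reject))
  mcse <- sd(falseRej) / sqrt(200)
  expect_lte(mean(falseRej), 0.05 + 2 * mcse)
})

test_that("the association grid has full cardinality and survives gaps", {
  ch <- fixCohort()
  est <- estimateProportions(ch, fixRef())
  panel <- generateClockPanel(fixRef(), fixDrift(), seed = 5)
  acc <- ageAccelTable(ch, panel, est)
  md <- sampleMetadata(ch)
  g <- runAssociationGrid(acc, est, md, variants = "eaa_resid",
                          mutual = FALSE)
  expect_equal(nrow(g), 6 * 12 * 3)               # clocks x cells x groups
  expect_true(all(g$q >= g$p - 1e-12, na.rm = TRUE))
  ## adult-only cohort: pediatric/newborn rows are emitted but unfit
  mdA <- md
  mdA$age <- pmax(mdA$age, 19)
  accA <- ageAccelTable(ch, panel[[1]], est)
  gA <- runAssociationGrid(accA, est, mdA, variants = "eaa_resid",
                           mutual = FALSE)
  expect_equal(nrow(gA), 12 * 3)
  expect_true(all(is.na(gA$beta[gA$age_group == "newborn"])))
  expect_false(anyNA(gA$beta[gA$age_group == "adult"]))
})

test_that("standardisation makes associations scale-free", {
  ch <- fixCohort()
  est <- estimateProportions(ch, fixRef())
  panel <- generateClockPanel(fixRef(), fixDrift(), seed = 5)
  acc <- ageAccelTable(ch, panel[[2]], est)
  md <- sampleMetadata(ch)
  g1 <- runAssociationGrid(acc, proportions(est), md,
                           variants = "eaa_resid", mutual = FALSE)
  g2 <- runAssociationGrid(acc, proportions(est) * 100, md,
                           variants = "eaa_resid", mutual = FALSE)
  expect_equal(g1$beta, g2$beta, tolerance = 1e-10)
  expect_equal(g1$p, g2$p, tolerance = 1e-10)
  expect_equal(g1$q, g2$q, tolerance = 1e-10)
})

test_that("missing sample keys are a join error", {
  ch <- fixCohort()
  est <- estimateProportions(ch, fixRef())
  panel <- generateClockPanel(fixRef(), fixDrift(), seed = 5)
  acc <- ageAccelTable(ch, panel[[1]], est)
  md <- sampleMetadata(ch)
  md$sample_id[1] <- "missing_sample"
  expect_error(runAssociationGrid(acc, est, md, variants = "eaa_resid",
                                  mutual = FALSE), "join error")
})
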