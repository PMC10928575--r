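toyClock <- function(weights, intercept = 0, family = "age_scale") {
  new("ClockDefinition", name = "toy", family = family, weights = weights,
      intercept = intercept, calibration = list(type = "identity"),
      intrinsicFraction = NA_real_)
}

test_that("mage is the sparse linear score over available CpGs", {
  ck <- toyClock(c(cpg1 = 1))
  b <- matrix(0.42, 1, 1, dimnames = list("s1", "cpg1"))
  expect_equal(unname(computeMAge(b, ck)$mage), 0.42)
  ## an absent CpG within the masking budget contributes zero
  w10 <- stats::setNames(rep(1, 10), paste0("cpg", 1:10))
  b10 <- matrix(0.3, 1, 9, dimnames = list(NULL, paste0("cpg", 1:9)))
  ev <- computeMAge(b10, toyClock(w10))
  expect_false(ev$masked)
  expect_equal(ev$mage, 2.7)
})

test_that("clock-level masking follows the >10% rule", {
  w <- stats::setNames(rep(1, 100), paste0("c", 1:100))
  ck <- toyClock(w)
  b <- matrix(0.5, 2, 100, dimnames = list(NULL, paste0("c", 1:100)))
  b[1, 1:11] <- NA
  b[2, 1:10] <- NA
  ev <- computeMAge(b, ck)
  expect_identical(ev$masked, c(TRUE, FALSE))
  expect_true(is.na(ev$mage[1]))
  ## NAs contribute zero for kept samples
  expect_equal(ev$mage[2], sum(b[2, ], na.rm = TRUE))
  ## imputation fills the gaps instead
  ev2 <- computeMAge(b, ck, imputeWith = stats::setNames(rep(0.5, 100),
                                                         paste0("c", 1:100)))
  expect_equal(ev2$mage[2], 50)
})

test_that("no resolvable clock CpGs is a configuration error", {
  b <- matrix(0.5, 1, 1, dimnames = list(NULL, "other"))
  expect_error(computeMAge(b, toyClock(c(cpg1 = 1))), "resolvable")
})

test_that("residual EAA honours its algebraic contracts", {
  age <- c(10, 20, 30, 40, 55)
  expect_equal(eaaResidual(age, age), rep(0, 5))
  expect_equal(eaaResidual(age + 7, age), rep(0, 5))
  set.seed(42)
  mage <- 2 * age + rnorm(5)
  r <- eaaResidual(mage, age)
  o <- olsOracle(cbind(1, age), mage)
  expect_lt(max(abs(r - o$residuals)), 1e-10)
  expect_lt(abs(mean(r)), 1e-8)
  expect_lt(abs(cov(r, age)), 1e-8)
})

test_that("degenerate designs are handled explicitly", {
  expect_error(eaaResidual(c(1, 2), c(1, 2)), "at least 3")
  expect_warning(r <- eaaResidual(c(5, 6, 7), c(0, 0, 0)), "constant age")
  expect_equal(r, c(-1, 0, 1))
})

test_that("difference EAA is the plain difference, age-scale only", {
  expect_equal(eaaDifference(50, 40), 10)
  age <- runif(100, 1, 99)
  mage <- age + rnorm(100)
  expect_equal(mean(eaaDifference(mage, age)), mean(mage) - mean(age),
               tolerance = 1e-12)
  expect_error(eaaDifference(1, 1, family = "pace_scale"), "age_scale")
})

test_that("IEAA residuals are orthogonal to every adjusted regressor", {
  ch <- fixCohort()
  est <- estimateProportions(ch, fixRef())
  md <- sampleMetadata(ch)
  ck <- generateClock(fixRef(), fixDrift(), intrinsicFraction = 0.4,
                      seed = 2)
  ev <- computeMAge(ch, ck)
  i11 <- computeIEAA(ev$mage, md$age, est, "eleven")
  p <- proportions(est)
  for (cell in cellTypes11())
    expect_lt(abs(cor(i11, p[, cell])), 1e-8)
  expect_lt(abs(cor(i11, md$age)), 1e-8)
  i6 <- computeIEAA(ev$mage, md$age, est, "six")
  agg <- aggregateSixCells(p)
  for (cell in colnames(agg))
    expect_lt(abs(cor(i6, agg[, cell])), 1e-8)
})

test_that("variance nests across the adjustment hierarchy", {
  ch <- fixCohort()
  est <- estimateProportions(ch, fixRef())
  md <- sampleMetadata(ch)
  for (ck in generateClockPanel(fixRef(), fixDrift(), seed = 5)[c(1, 4, 6)]) {
    ev <- computeMAge(ch, ck)
    vE <- var(eaaResidual(ev$mage, md$age))
    v6 <- var(computeIEAA(ev$mage, md$age, est, "six"))
    v11 <- var(computeIEAA(ev$mage, md$age, est, "eleven"))
    expect_lte(v11, v6 + 1e-10)
    expect_lte(v6, vE + 1e-10)
  }
})

test_that("a pure-composition clock is annihilated by eleven-cell adjustment", {
  ck <- generateClock(fixRef(), fixDrift(), intrinsicFraction = 0, seed = 3)
  ch <- generateCohort(60, bloodCompositionModel(), fixRef(),
                       driftModel = fixDrift(), noisePrecision = Inf,
                       seed = 5)
  est <- estimateProportions(ch, fixRef())
  md <- sampleMetadata(ch)
  ev <- computeMAge(ch, ck)
  i11 <- computeIEAA(ev$mage, md$age, est, "eleven")
  expect_lt(var(i11), 1e-10 * var(ev$mage))
})

test_that("the acceleration table has the documented shape", {
  ch <- fixCohort()
  est <- estimateProportions(ch, fixRef())
  panel <- generateClockPanel(fixRef(), fixDrift(), seed = 5)
  acc <- ageAccelTable(ch, panel, est)
  expect_equal(nrow(acc), 80 * 6)
  expect_true(all(c("mage", "eaa_resid", "eaa_diff", "ieaa6", "ieaa11")
                  %in% colnames(acc)))
  expect_true(all(is.na(acc$eaa_diff[acc$family != "age_scale"])))
  expect_false(anyNA(acc$eaa_diff[acc$family == "age_scale"]))
})
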