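mkPool <- function(nCase, nCtrl, seed) {
  md <- simulateSampleMetadata(nCase + nCtrl, seed = seed, newbornFrac = 0)
  md$disease <- rep(c("case", "none"), c(nCase, nCtrl))
  md
}

test_that("an identical pool matches at zero distance", {
  cases <- data.frame(sample_id = paste0("c", 1:10), age = 20:29,
                      sex = "Male", ancestry = "European")
  controls <- cases
  controls$sample_id <- paste0("k", 1:10)
  mt <- matchControls(cases, controls)
  expect_equal(nrow(mt$pairs), 10)
  expect_true(all(mt$pairs$distance == 0))
  expect_false(anyDuplicated(mt$pairs$control_id) > 0)
})

test_that("the nearest eligible control is chosen", {
  cases <- data.frame(sample_id = "c1", age = 50, sex = "F", ancestry = "E")
  controls <- data.frame(sample_id = c("k1", "k2"), age = c(49, 60),
                         sex = "F", ancestry = "E")
  mt <- matchControls(cases, controls)
  expect_identical(mt$pairs$control_id, "k1")
  expect_equal(mt$pairs$distance, 1)
})

test_that("exact variables are balanced and unmatched cases reported", {
  md <- mkPool(60, 400, seed = 21)
  cases <- md[md$disease == "case", ]
  cases$ancestry[1] <- "Martian"                   # no eligible control
  expect_warning(
    mt <- matchControls(cases, md[md$disease == "none", ]),
    "could not be matched")
  expect_identical(mt$unmatched, cases$sample_id[1])
  expect_identical(mt$matchedCases$sex, mt$matchedControls$sex)
  expect_identical(mt$matchedCases$ancestry, mt$matchedControls$ancestry)
  expect_false(anyDuplicated(mt$pairs$control_id) > 0)
})

test_that("greedy matching approaches the optimal assignment (DP oracle)", {
  md <- mkPool(80, 400, seed = 22)
  cases <- md[md$disease == "case", ]
  ctrl <- md[md$disease == "none", ]
  mt <- matchControls(cases, ctrl)
  strat <- paste(mt$matchedCases$sex, mt$matchedCases$ancestry)
  stratC <- paste(ctrl$sex, ctrl$ancestry)
  opt <- sum(vapply(unique(strat), function(s)
    optimalMatchDistance1d(mt$matchedCases$age[strat == s],
                           ctrl$age[stratC == s]), numeric(1)))
  expect_lte(sum(mt$pairs$distance), 1.10 * opt + 1e-9)
})

test_that("the DP assignment oracle is itself exact (brute force)", {
  perm4 <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perm4 <- perm4[apply(perm4, 1, function(r) length(unique(r)) == 4), ]
  set.seed(23)
  for (i in 1:20) {
    x <- runif(4, 0, 50)
    y <- runif(6, 0, 50)
    ## enumerate every injection of 4 cases into 6 controls
    brute <- min(apply(t(utils::combn(6, 4)), 1, function(idx)
      min(apply(perm4, 1, function(pp) sum(abs(x - y[idx[pp]]))))))
    expect_equal(optimalMatchDistance1d(x, y), brute, tolerance = 1e-12)
  }
})

test_that("matching never worsens age imbalance", {
  for (s in 24:26) {
    md <- mkPool(70, 500, seed = s)
    md$age[md$disease == "case"] <- pmin(md$age[md$disease == "case"] + 10, 99)
    cases <- md[md$disease == "case", ]
    ctrl <- md[md$disease == "none", ]
    smdBefore <- abs(mean(cases$age) - mean(ctrl$age)) /
      sd(c(cases$age, ctrl$age))
    mt <- matchControls(cases, ctrl)
    smdAfter <- abs(mean(mt$matchedCases$age) - mean(mt$matchedControls$age)) /
      sd(c(mt$matchedCases$age, mt$matchedControls$age))
    expect_lte(smdAfter, smdBefore)
  }
})

test_that("group effects reduce to the pooled-variance t-test", {
  expect_equal(groupEffect(c(1, 2, 3, 1, 2, 3), rep(c(1, 0), each = 3))$beta,
               0)
  set.seed(27)
  y <- rnorm(40)
  st <- rep(c(1, 0), 20)
  f <- groupEffect(y, st)
  tt <- t.test(y[st == 1], y[st == 0], var.equal = TRUE)
  expect_equal(f$p, tt$p.value, tolerance = 1e-12)
  expect_equal(f$beta, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  expect_error(groupEffect(y, rep(1, 40)), "non-empty")
})

test_that("permuted labels yield no composition differences", {
  ch <- fixCohort()
  est <- estimateProportions(ch, fixRef())
  set.seed(28)
  anyReject <- vapply(1:40, function(i) {
    any(compositionDifference(est, sample(rep(c(TRUE, FALSE), 40)))$reject)
  }, logical(1))
  expect_lte(mean(anyReject), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 40))
})

test_that("the confounding report grid is complete", {
  ch <- generateCohort(120, bloodCompositionModel(), fixRef(),
                       driftModel = fixDrift(), diseasePrev = 0.4,
                       newbornFrac = 0, seed = 29)
  est <- estimateProportions(ch, fixRef())
  panel <- generateClockPanel(fixRef(), fixDrift(), seed = 5)
  acc <- ageAccelTable(ch, panel, est)
  rep_ <- confoundingReport(acc, sampleMetadata(ch))
  expect_equal(nrow(rep_), 6 * 3)
  expect_setequal(unique(rep_$variant), c("eaa_resid", "ieaa6", "ieaa11"))
  expect_false(anyNA(rep_$p))
})
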