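test_that("noiseless mixtures equal the exact linear combination", {
  ch <- generateCohort(5, detComposition(), fixRef(),
                       driftModel = fixDrift(), noisePrecision = Inf,
                       intrinsicSd = 0, seed = 3)
  W <- trueProportions(ch)
  R <- meanBeta(fixRef())
  beta <- t(betaMatrix(ch))
  expect_equal(beta[, colnames(R)], W %*% R, tolerance = 1e-12)
})

test_that("drift CpGs move linearly with age", {
  dm <- new("DriftModel", cpgIds = c("cgDa", "cgDb"),
            base = c(0.3, 0.4), slope = c(0.002, 0.002))
  md <- data.frame(sample_id = c("s1", "s2"), age = c(0, 50),
                   sex = "Male", ancestry = "European", disease = "none")
  ch <- generateCohort(2, detComposition(), fixRef(), driftModel = dm,
                       noisePrecision = Inf, intrinsicSd = 0,
                       metadata = md, seed = 5)
  b <- betaMatrix(ch)
  expect_equal(unname(b["cgDa", "s2"] - b["cgDa", "s1"]), 0.1,
               tolerance = 1e-12)
  expect_equal(unname(b["cgDb", "s2"] - b["cgDb", "s1"]), 0.1,
               tolerance = 1e-12)
})

test_that("observation noise follows the Beta mean-precision law", {
  ## constant composition -> constant mu per marker CpG
  ch <- generateCohort(4000, detComposition(), fixRef(),
                       driftModel = fixDrift(), noisePrecision = 100,
                       intrinsicSd = 0,
                       metadata = data.frame(
                         sample_id = sprintf("s%04d", 1:4000), age = 50,
                         sex = "Male", ancestry = "European",
                         disease = "none"),
                       seed = 3)
  beta <- t(betaMatrix(ch))
  mu <- drop(trueProportions(ch)[1, ] %*% meanBeta(fixRef()))
  sel <- which(mu > 0.2 & mu < 0.8)
  expect_gt(length(sel), 5)
  for (j in sel) {
    theo <- mu[j] * (1 - mu[j]) / 101
    expect_lt(abs(var(beta[, names(mu)[j]]) - theo) / theo, 0.10)
  }
})

test_that("cohorts are deterministic given the seed and stay in range", {
  a <- generateCohort(30, bloodCompositionModel(), fixRef(),
                      driftModel = fixDrift(), seed = 9)
  b <- generateCohort(30, bloodCompositionModel(), fixRef(),
                      driftModel = fixDrift(), seed = 9)
  expect_identical(betaMatrix(a), betaMatrix(b))
  expect_identical(trueProportions(a), trueProportions(b))
  expect_true(all(betaMatrix(a) >= 0 & betaMatrix(a) <= 1))
  c_ <- generateCohort(30, bloodCompositionModel(), fixRef(),
                       driftModel = fixDrift(), seed = 10)
  expect_false(identical(betaMatrix(a), betaMatrix(c_)))
})

test_that("drift CpGs must be disjoint from reference markers", {
  dm <- new("DriftModel", cpgIds = markerCpGs(fixRef())[1],
            base = 0.3, slope = 1e-4)
  expect_error(generateCohort(5, detComposition(), fixRef(),
                              driftModel = dm, seed = 1), "disjoint")
})

test_that("purified cohorts are pure and carry unit truth rows", {
  pur <- generatePurifiedCohorts(fixRef(), fixDrift(), nPerType = 5,
                                 seed = 4)
  expect_named(pur, cellTypes12())
  for (cell in c("Neu", "CD8nv")) {
    tp <- trueProportions(pur[[cell]])
    expect_equal(unname(tp[, cell]), rep(1, 5))
    expect_equal(sum(tp), 5)
  }
})
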