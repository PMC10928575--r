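test_that("pure reference profiles are recovered as unit vectors", {
  R <- meanBeta(fixRef())
  for (constraint in c("le_one", "eq_one")) {
    est <- estimateProportions(R, fixRef(), sumConstraint = constraint)
    expect_lt(max(abs(proportions(est) - diag(12))), 1e-8)
    expect_lt(max(fitResidual(est)), 1e-8)
  }
})

test_that("an exact convex combination is recovered exactly", {
  R <- meanBeta(fixRef())
  b <- matrix(0.5 * R["CD4nv", ] + 0.5 * R["Neu", ], nrow = 1,
              dimnames = list("mix", colnames(R)))
  w <- proportions(estimateProportions(b, fixRef()))[1, ]
  expect_lt(abs(w["CD4nv"] - 0.5), 1e-6)
  expect_lt(abs(w["Neu"] - 0.5), 1e-6)
  expect_lt(sum(w[setdiff(cellTypes12(), c("CD4nv", "Neu"))]), 1e-6)
})

test_that("noiseless synthetic cohorts are recovered to solver precision", {
  ch <- generateCohort(40, bloodCompositionModel(), fixRef(),
                       driftModel = fixDrift(), noisePrecision = Inf,
                       seed = 6)
  est <- estimateProportions(ch, fixRef())
  expect_lt(max(abs(proportions(est) - trueProportions(ch))), 1e-6)
})

test_that("noisy estimates agree with an independent QP oracle", {
  skip_if_not_installed("pracma")
  ch <- generateCohort(60, bloodCompositionModel(), fixRef(),
                       driftModel = fixDrift(), noisePrecision = 100,
                       seed = 7)
  est <- estimateProportions(ch, fixRef())
  R <- meanBeta(fixRef())
  B <- t(betaMatrix(ch))[, colnames(R)]
  M <- 1e4
  A2 <- rbind(cbind(t(R), 0), c(rep(M, nrow(R)), M))
  for (i in seq_len(nrow(B))) {
    w <- pracma::lsqnonneg(A2, c(B[i, ], M))$x[seq_len(12)]
    expect_lt(max(abs(w - proportions(est)[i, ])), 1e-6)
  }
  expect_lt(max(colMeans(abs(proportions(est) - trueProportions(ch)))), 0.05)
})

test_that("estimation error shrinks as observation noise falls", {
  maes <- vapply(c(25, 100, 400), function(prec) {
    ch <- generateCohort(200, bloodCompositionModel(), fixRef(),
                         driftModel = fixDrift(), noisePrecision = prec,
                         seed = 50)
    est <- estimateProportions(ch, fixRef())
    mean(abs(proportions(est) - trueProportions(ch)))
  }, numeric(1))
  expect_true(all(diff(maes) < 0))
})

test_that("constraints hold on every output row", {
  ch <- generateCohort(50, bloodCompositionModel(), fixRef(),
                       driftModel = fixDrift(), noisePrecision = 25,
                       seed = 31)
  for (constraint in c("le_one", "eq_one")) {
    p <- proportions(estimateProportions(ch, fixRef(),
                                         sumConstraint = constraint))
    expect_true(all(p >= -1e-8))
    expect_true(all(rowSums(p) <= 1 + 1e-8))
    if (constraint == "eq_one")
      expect_lt(max(abs(rowSums(p) - 1)), 1e-8)
  }
})

test_that("permuting reference rows permutes the estimates identically", {
  ref <- fixRef()
  perm <- rev(seq_len(12))
  refP <- new("ReferenceLibrary", cellTypes = cellTypes(ref)[perm],
              meanBeta = meanBeta(ref)[perm, ],
              precision = ref@precision,
              markerType = ref@markerType)
  ch <- generateCohort(20, bloodCompositionModel(), ref,
                       driftModel = fixDrift(), noisePrecision = 100,
                       seed = 13)
  a <- proportions(estimateProportions(ch, ref))
  b <- proportions(estimateProportions(ch, refP))
  expect_equal(a, b[, colnames(a)], tolerance = 1e-10)
})

test_that("the >10% missing-library rule masks exactly at the boundary", {
  b <- matrix(0.5, 3, 100, dimnames = list(NULL, paste0("cg", 1:100)))
  b[2, 1:10] <- NA
  b[3, 1:11] <- NA
  m <- applyLibraryMasking(b, paste0("cg", 1:100))
  expect_identical(m, c(FALSE, FALSE, TRUE))
  ## absent columns count as missing too
  m2 <- applyLibraryMasking(b[, 1:89], paste0("cg", 1:100))
  expect_identical(m2, c(TRUE, TRUE, TRUE))
})

test_that("masked samples come back all-NA while others are solved", {
  ch <- generateCohort(6, bloodCompositionModel(), fixRef(),
                       driftModel = fixDrift(), noisePrecision = 100,
                       seed = 14)
  B <- t(betaMatrix(ch))
  lib <- markerCpGs(fixRef())
  B[1, lib[1:5]] <- NA                            # 5/36 ~ 14% -> masked
  B[2, lib[1:3]] <- NA                            # 3/36 ~ 8% -> kept
  est <- estimateProportions(B, fixRef())
  expect_true(maskedSamples(est)[1])
  expect_false(maskedSamples(est)[2])
  expect_true(all(is.na(proportions(est)[1, ])))
  expect_false(anyNA(proportions(est)[2, ]))
})

test_that("degenerate references are rejected", {
  ref <- fixRef()
  m <- meanBeta(ref)
  m["Eos", ] <- m["Bas", ]                       # rank-deficient
  refBad <- ref
  refBad@meanBeta <- m
  b <- matrix(0.5, 2, ncol(m), dimnames = list(NULL, colnames(m)))
  expect_error(estimateProportions(b, refBad), "singular|rank")
  ## too few shared markers for one cell type
  b2 <- b[, colnames(m)[ref@markerType != "NK"]]
  expect_error(estimateProportions(b2, ref), "reference mismatch")
})
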