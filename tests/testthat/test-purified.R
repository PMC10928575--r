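test_that("a perfect age tracker scores perfectly within each cell type", {
  ## manual clock: one drift CpG, weight 1/slope -> mage = age exactly
  dm <- fixDrift()
  ck <- new("ClockDefinition", name = "exact", family = "age_scale",
            weights = stats::setNames(1 / dm@slope[1], dm@cpgIds[1]),
            intercept = -dm@base[1] / dm@slope[1],
            calibration = list(type = "identity"),
            intrinsicFraction = 1)
  pur <- generatePurifiedCohorts(fixRef(), dm, nPerType = 6,
                                 noisePrecision = Inf, intrinsicSd = 0,
                                 seed = 8)
  pe <- suppressWarnings(evaluatePurified(pur, ck))  # zero-residual fits
  expect_equal(nrow(pe$stats), 12)
  expect_true(all(pe$stats$r > 1 - 1e-10))
  expect_true(all(pe$stats$rmse < 1e-8))
  expect_true(all(pe$stats$p < 1e-10))
  expect_equal(pe$stats$r2, pe$stats$r^2, tolerance = 1e-12)
})

test_that("pure-composition clocks have null slopes in purified cells", {
  ck <- generateClock(fixRef(), fixDrift(), intrinsicFraction = 0, seed = 3)
  ## within one pure cell type the composition score is constant, so the
  ## slope test is null: rejections near nominal over repeated panels
  rej <- 0L
  nSim <- 200
  for (s in seq_len(nSim)) {
    md <- simulateSampleMetadata(12, seed = 9000 + s, newbornFrac = 0,
                                 ageRange = c(20, 70), idPrefix = "p")
    logits <- stats::setNames(rep(-60, 12), cellTypes12())
    logits["CD4nv"] <- 0
    ch <- generateCohort(12, newCompositionModel(logits), fixRef(),
                         driftModel = fixDrift(), noisePrecision = 100,
                         metadata = md, seed = 9500 + s)
    ev <- computeMAge(ch, ck)
    p <- summary(stats::lm(ev$mage ~ md$age))$coefficients[2, 4]
    if (p < 0.05) rej <- rej + 1L
  }
  expect_lt(rej / nSim, 0.05 + 2.5 * sqrt(0.05 * 0.95 / nSim))
})

test_that("planted memory offsets order the pooled purified EAA", {
  pur <- generatePurifiedCohorts(fixRef(), fixDrift(), nPerType = 40,
                                 seed = 10)
  panel <- generateClockPanel(fixRef(), fixDrift(), seed = 5)
  pe <- evaluatePurified(pur, panel)
  ee <- stats::aggregate(eaa_pooled ~ cell + clock, pe$eaa, mean)
  for (ck in unique(ee$clock)) {
    expect_lt(ee$eaa_pooled[ee$cell == "CD8nv" & ee$clock == ck],
              ee$eaa_pooled[ee$cell == "CD8mem" & ee$clock == ck])
  }
  ## within-cell EAA is recentred by construction
  expect_lt(max(abs(tapply(pe$eaa$eaa_within,
                           paste(pe$eaa$cell, pe$eaa$clock), mean))), 1e-8)
})

test_that("tiny cell panels are skipped with a warning", {
  pur <- generatePurifiedCohorts(fixRef(), fixDrift(), nPerType = 4, seed = 2)
  tiny <- generatePurifiedCohorts(fixRef(), fixDrift(), nPerType = 2, seed = 3)
  pur[["NK"]] <- tiny[["NK"]]
  ck <- generateClockPanel(fixRef(), fixDrift(), seed = 5)[[1]]
  ws <- testthat::capture_warnings(pe <- evaluatePurified(pur, ck))
  expect_true(any(grepl("fewer than 3", ws)))
  expect_false("NK" %in% pe$stats$cell)
})
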