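#' Reproducible study experiments
#'
#' Each \code{experiment*} function re-runs one of the package's planted
#' synthetic studies end to end (generate, deconvolve, evaluate clocks,
#' model) and returns the summary quantities. They are used by the test
#' suite and by \code{scripts/acceptance.R}, and are the recommended
#' entry points for reproducing the package's headline numbers.
#'
#' @param seed Integer seed controlling every random draw.
#' @name immunoEAA-experiments
NULL

## shared study fixtures: reference, drift panel, clock panel
studyFixtures <- function(seed, scenario = defaultScenario()) {
  ref <- generateReferenceLibrary(scenario$nCpgsPerType,
                                  delta = scenario$refDelta,
                                  seed = deriveSeed(seed, 900))
  dm <- makeDriftModel(scenario$nDriftCpgs, scenario$driftSlope,
                       seed = deriveSeed(seed, 901))
  clocks <- generateClockPanel(ref, dm,
                               composition = scenarioComposition(scenario),
                               seed = deriveSeed(seed, 902))
  list(scenario = scenario, reference = ref, driftModel = dm,
       clocks = clocks)
}

#' @rdname immunoEAA-experiments
#' @param nNoisy Noisy-cohort size.
#' @return \code{experimentDeconvolution}: noiseless max recovery error,
#'   noisy per-cell MAE (worst cell), and max disagreement with a
#'   penalty-formulation NNLS oracle (NA when \pkg{pracma} is absent).
#' @export
experimentDeconvolution <- function(seed = 1, nNoisy = 200) {
  fx <- studyFixtures(seed)
  cm <- scenarioComposition(fx$scenario)
  ch0 <- generateCohort(100, cm, fx$reference, driftModel = fx$driftModel,
                        noisePrecision = Inf, seed = deriveSeed(seed, 10))
  est0 <- estimateProportions(ch0, fx$reference)
  maxErr <- max(abs(proportions(est0) - trueProportions(ch0)))

  ch <- generateCohort(nNoisy, cm, fx$reference, driftModel = fx$driftModel,
                       noisePrecision = 100, seed = deriveSeed(seed, 11))
  est <- estimateProportions(ch, fx$reference)
  mae <- max(colMeans(abs(proportions(est) - trueProportions(ch))))

  oracleDiff <- NA_real_
  if (requireNamespace("pracma", quietly = TRUE)) {
    R <- meanBeta(fx$reference)
    B <- t(betaMatrix(ch))[, colnames(R)]
    M <- 1e4
    ## penalty formulation: slack cell enforces sum(w) + s = 1
    A2 <- rbind(cbind(t(R), 0), c(rep(M, ncol(R) * 0 + nrow(R)), M))
    oracleDiff <- 0
    for (i in seq_len(nrow(B))) {
      b2 <- c(B[i, ], M)
      w <- pracma::lsqnonneg(A2, b2)$x[seq_len(nrow(R))]
      oracleDiff <- max(oracleDiff, max(abs(w - proportions(est)[i, ])))
    }
  }
  list(noiselessMaxError = maxErr, noisyMae = mae,
       oracleMaxDiff = oracleDiff, n = nNoisy)
}

#' @rdname immunoEAA-experiments
#' @param n Cohort size.
#' @return \code{experimentResidualContracts}: worst-case violations of
#'   the residual contracts across the default clock panel.
#' @export
experimentResidualContracts <- function(seed = 1, n = 800) {
  fx <- studyFixtures(seed)
  ch <- scenarioCohort(fx$scenario, reference = fx$reference,
                       driftModel = fx$driftModel, seed = deriveSeed(seed, 20),
                       n = n)
  props <- estimateProportions(ch, fx$reference)
  md <- sampleMetadata(ch)
  accel <- ageAccelTable(ch, fx$clocks, props)
  p12 <- proportions(props)
  meanAbs <- covAbs <- orth <- nest <- 0
  for (clk in unique(accel$clock)) {
    a <- accel[accel$clock == clk, ]
    e <- a$eaa_resid
    sde <- stats::sd(e)
    meanAbs <- max(meanAbs, abs(mean(e)) / sde)
    covAbs <- max(covAbs, abs(stats::cov(e, md$age)) / (sde * stats::sd(md$age)))
    for (cell in cellTypes11())
      orth <- max(orth, abs(stats::cor(a$ieaa11, p12[, cell])))
    agg <- aggregateSixCells(p12)
    for (cell in colnames(agg))
      orth <- max(orth, abs(stats::cor(a$ieaa6, agg[, cell])))
    v <- c(stats::var(a$ieaa11), stats::var(a$ieaa6), stats::var(e))
    nest <- max(nest, v[1] - v[2], v[2] - v[3])
  }
  list(eaaMeanAbs = meanAbs, eaaAgeCorrAbs = covAbs,
       ieaaCellCorrMax = orth, nestingViolation = nest, n = n)
}

#' @rdname immunoEAA-experiments
#' @param nReps Number of seeded replicates.
#' @return \code{experimentAssociationStudy}: per-cell sign+FDR recovery
#'   counts for the planted naive/memory effects (adult group,
#'   composition-sensitive clock) and the number of cell types whose mean
#'   absolute association satisfies the IEAA-11 < IEAA-6 < EAA
#'   attenuation ordering across the clock panel.
#' @export
experimentAssociationStudy <- function(seed = 1, nReps = 20, n = 2000) {
  fx <- studyFixtures(seed)
  cm <- scenarioComposition(fx$scenario)
  signClock <- generateClock(fx$reference, fx$driftModel, "age_scale",
                             intrinsicFraction = 0.35, composition = cm,
                             name = "signClock", seed = deriveSeed(seed, 53))
  clocks <- c(fx$clocks, list(signClock = signClock))
  planted <- c(Bnv = -1, CD4nv = -1, CD8nv = -1,
               Bmem = 1, CD4mem = 1, CD8mem = 1)
  hits <- stats::setNames(integer(length(planted)), names(planted))
  grids <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    ch <- generateCohort(n, cm, fx$reference, driftModel = fx$driftModel,
                         seed = deriveSeed(seed, 1000 + r))
    props <- estimateProportions(ch, fx$reference)
    md <- sampleMetadata(ch)
    accel <- ageAccelTable(ch, clocks, props)
    g <- runAssociationGrid(accel, props, md,
                            variants = c("eaa_resid", "ieaa6", "ieaa11"),
                            mutual = FALSE)
    g <- g[g$age_group == "adult", ]
    ## planted-sign recovery: per-cell model, adult group, canonical clock
    sig <- g[g$clock == "signClock" & g$variant == "eaa_resid", ]
    for (cell in names(planted)) {
      row <- sig[sig$cell == cell, ]
      if (nrow(row) == 1 && !is.na(row$q) &&
          sign(row$beta) == planted[cell] && row$q < 0.05)
        hits[cell] <- hits[cell] + 1L
    }
    grids[[r]] <- g[g$clock != "signClock", ]
  }
  G <- do.call(rbind, grids)
  mb <- stats::aggregate(abs(G$beta),
                         by = list(cell = G$cell, variant = G$variant),
                         FUN = mean, na.rm = TRUE)
  absBeta <- matrix(NA_real_, 12, 3,
                    dimnames = list(cellTypes12(),
                                    c("eaa_resid", "ieaa6", "ieaa11")))
  for (i in seq_len(nrow(mb)))
    absBeta[mb$cell[i], mb$variant[i]] <- mb$x[i]
  ordered <- sum(absBeta[, "ieaa11"] < absBeta[, "ieaa6"] &
                 absBeta[, "ieaa6"] < absBeta[, "eaa_resid"])
  list(signRecoveryMin = min(hits), signRecovery = hits,
       attenuationCellsOrdered = as.integer(ordered),
       meanAbsBeta = absBeta, nReps = nReps, n = n)
}

#' @rdname immunoEAA-experiments
#' @param nCohorts Number of independent null cohorts.
#' @param fitsPerCohort Independent-noise cell regressors tested per
#'   cohort.
#' @return \code{experimentTypeIError}: empirical rejection rate of the
#'   per-cell model at p < 0.05 under the null (intrinsic clock, cell
#'   regressor replaced by independent noise, so the fits are mutually
#'   independent and the binomial band applies).
#' @export
experimentTypeIError <- function(seed = 1, nCohorts = 10,
                                 fitsPerCohort = 50, n = 300) {
  fx <- studyFixtures(seed)
  cmNull <- scenarioComposition(fx$scenario)
  cmNull@ageSlopes <- numeric(12)
  cmNull@diseaseShifts <- numeric(12)
  clock <- generateClock(fx$reference, fx$driftModel, "age_scale",
                         intrinsicFraction = 1, composition = cmNull,
                         name = "nullClock", seed = deriveSeed(seed, 5))
  ps <- numeric(0)
  for (r in seq_len(nCohorts)) {
    ch <- generateCohort(n, cmNull, fx$reference,
                         driftModel = fx$driftModel,
                         seed = deriveSeed(seed, 2000 + r))
    md <- sampleMetadata(ch)
    ev <- computeMAge(ch, clock)
    yz <- zscoreByGroup(eaaResidual(ev$mage, md$age))
    ps <- c(ps, withSeed(deriveSeed(seed, 2500 + r), {
      vapply(seq_len(fitsPerCohort), function(j)
        fitCellModel(yz, stats::rnorm(n), md)$p, numeric(1))
    }))
  }
  list(typeIRate = mean(ps < 0.05), nFits = length(ps))
}

#' @rdname immunoEAA-experiments
#' @param oracleN Size of the ground-truth cohort used to compute the
#'   planted effect-magnitude ranking (evaluated on true proportions).
#' @return \code{experimentVarianceRecovery}: how often the planted
#'   dominant covariate block attains the largest partial R-squared, and
#'   the Spearman agreement of the additional-R-squared cell ranking with
#'   the generator's planted ranking.
#' @export
experimentVarianceRecovery <- function(seed = 1, nReps = 20, n = 2000,
                                       oracleN = 12000) {
  scA <- defaultScenario(diseasePrev = 0.15)
  fx <- studyFixtures(seed, scA)
  ## planted ranking oracle: true proportions, large n
  orc <- scenarioCohort(scA, reference = fx$reference,
                        driftModel = fx$driftModel,
                        seed = deriveSeed(seed, 3999), n = oracleN)
  accO <- ageAccelTable(orc, fx$clocks$mitoticClock, trueProportions(orc))
  dO <- decomposeEaaVariance(accO$eaa_resid, trueProportions(orc),
                             sampleMetadata(orc))

  scB <- defaultScenario(diseasePrev = 0.3, diseaseDriftYears = 25,
                         compositionDisease = FALSE)
  intrClock <- generateClock(fx$reference, fx$driftModel, "age_scale",
                             intrinsicFraction = 0.98,
                             composition = scenarioComposition(scA),
                             name = "intrinsicClock",
                             seed = deriveSeed(seed, 6))
  cellsWin <- diseaseWin <- 0L
  rhos <- numeric(nReps)
  for (r in seq_len(nReps)) {
    chA <- scenarioCohort(scA, reference = fx$reference,
                          driftModel = fx$driftModel,
                          seed = deriveSeed(seed, 3000 + r), n = n)
    pA <- estimateProportions(chA, fx$reference)
    accA <- ageAccelTable(chA, fx$clocks$mitoticClock, pA)
    dA <- decomposeEaaVariance(accA$eaa_resid, pA, sampleMetadata(chA))
    if (names(which.max(dA$partial)) == "cells") cellsWin <- cellsWin + 1L
    rhos[r] <- stats::cor(dA$additional, dO$additional, method = "spearman")

    chB <- scenarioCohort(scB, reference = fx$reference,
                          driftModel = fx$driftModel,
                          seed = deriveSeed(seed, 3500 + r), n = n)
    pB <- estimateProportions(chB, fx$reference)
    accB <- ageAccelTable(chB, intrClock, pB)
    dB <- decomposeEaaVariance(accB$eaa_resid, pB, sampleMetadata(chB))
    if (names(which.max(dB$partial)) == "disease") diseaseWin <- diseaseWin + 1L
  }
  list(cellsDominantWins = cellsWin, diseaseDominantWins = diseaseWin,
       spearmanMean = mean(rhos), nReps = nReps, n = n)
}

#' Exact optimal 1:1 assignment distance on one dimension
#'
#' Dynamic-programming benchmark for the greedy matcher: with cases and
#' controls sorted, an optimal assignment of all cases to distinct
#' controls minimising total |distance| never crosses, giving an exact
#' O(cases x controls) recursion. Applied within exact strata it yields
#' the optimal total age distance for comparison with
#' \code{\link{matchControls}}.
#'
#' @param caseVals,controlVals Numeric vectors (controls at least as many
#'   as cases).
#' @return Minimal total absolute distance.
#' @export
optimalMatchDistance1d <- function(caseVals, controlVals) {
  x <- sort(caseVals)
  y <- sort(controlVals)
  nx <- length(x)
  ny <- length(y)
  if (nx > ny) stop("need at least as many controls as cases")
  prev <- c(0, rep(Inf, nx))
  for (j in seq_len(ny)) {
    cur <- prev
    for (i in seq_len(min(j, nx)))
      cur[i + 1] <- min(prev[i + 1], prev[i] + abs(x[i] - y[j]))
    prev <- cur
  }
  prev[nx + 1]
}

#' @rdname immunoEAA-experiments
#' @param mode "composition" (disease shifts cell composition only) or
#'   "intrinsic" (disease adds to the intrinsic aging signal only).
#' @param nPool Pool size from which cases and matched controls are
#'   drawn (prevalence 0.15 yields roughly 350-430 case/control pairs).
#' @return \code{experimentConfounding}: counts of replicates with a
#'   significant raw-EAA group effect and significant/non-significant
#'   IEAA effects, matching balance metrics, and the greedy/optimal total
#'   age-distance ratio.
#' @export
experimentConfounding <- function(seed = 1, nReps = 20,
                                  mode = c("composition", "intrinsic"),
                                  nPool = 2600) {
  mode <- match.arg(mode)
  sc <- if (mode == "composition") defaultScenario(diseasePrev = 0.15)
        else defaultScenario(diseasePrev = 0.15, diseaseDriftYears = 12,
                             compositionDisease = FALSE)
  fx <- studyFixtures(seed)
  ## composition mode: an inflammation-sensitive pace clock (neutrophils
  ## as a strong positive driver) shows the composition-mediated effect;
  ## intrinsic mode: an intrinsic-dominated age clock carries the direct
  ## effect through full cell adjustment
  clock <- if (mode == "composition") {
    g <- defaultCellLoadings()
    g["Neu"] <- 0.5
    generateClock(fx$reference, fx$driftModel, "pace_scale",
                  intrinsicFraction = 0.25, cellLoadings = g,
                  composition = scenarioComposition(fx$scenario),
                  name = "inflammationClock", seed = deriveSeed(seed, 7))
  } else fx$clocks$ageClock1
  rawSig <- i6Sig <- i11Sig <- 0L
  distRatio <- 1
  meanDist <- balanced <- numeric(nReps)
  for (r in seq_len(nReps)) {
    ch <- scenarioCohort(sc, reference = fx$reference,
                         driftModel = fx$driftModel,
                         seed = deriveSeed(seed, 4000 + r), n = nPool)
    md <- sampleMetadata(ch)
    mt <- matchControls(md[md$disease != "none", ], md[md$disease == "none", ])
    meanDist[r] <- mean(mt$pairs$distance)
    mc <- mt$matchedCases
    mk <- mt$matchedControls
    balanced[r] <- all(mc$sex == mk$sex) && all(mc$ancestry == mk$ancestry)
    ## optimal total distance within exact strata
    strat <- paste(mc$sex, mc$ancestry)
    ctrl <- md[md$disease == "none", ]
    stratC <- paste(ctrl$sex, ctrl$ancestry)
    opt <- sum(vapply(unique(strat), function(s)
      optimalMatchDistance1d(mc$age[strat == s], ctrl$age[stratC == s]),
      numeric(1)))
    if (opt > 0)
      distRatio <- max(distRatio, sum(mt$pairs$distance) / opt)
    sel <- md$sample_id %in% c(mt$pairs$case_id, mt$pairs$control_id)
    props <- estimateProportions(ch, fx$reference)
    accel <- ageAccelTable(ch, clock, props)
    rep_ <- confoundingReport(accel[accel$sample_id %in% md$sample_id[sel], ],
                              md[sel, ])
    if (rep_$p[rep_$variant == "eaa_resid"] < 0.05) rawSig <- rawSig + 1L
    if (rep_$p[rep_$variant == "ieaa6"] < 0.05) i6Sig <- i6Sig + 1L
    if (rep_$p[rep_$variant == "ieaa11"] < 0.05) i11Sig <- i11Sig + 1L
  }
  list(mode = mode, rawSignificant = rawSig, ieaa6Significant = i6Sig,
       ieaa11Significant = i11Sig, meanAgeDistance = mean(meanDist),
       exactBalanceAll = all(balanced > 0),
       greedyVsOptimalRatio = distRatio, nReps = nReps)
}

#' @rdname immunoEAA-experiments
#' @param nPerType Purified samples per cell type.
#' @return \code{experimentPurifiedDegradation}: the drop in
#'   age-tracking R-squared of a composition-dominated clock between the
#'   mixed cohort and purified cell types, and how often the pooled EAA
#'   of CD8nv lies below CD8mem.
#' @export
experimentPurifiedDegradation <- function(seed = 1, nReps = 5,
                                          nPerType = 40) {
  fx <- studyFixtures(seed)
  cm <- scenarioComposition(fx$scenario)
  clock <- fx$clocks$mitoticClock   # intrinsic fraction 0.15
  drops <- numeric(nReps)
  cd8ok <- 0L
  for (r in seq_len(nReps)) {
    mixed <- generateCohort(1500, cm, fx$reference,
                            driftModel = fx$driftModel,
                            seed = deriveSeed(seed, 5000 + r))
    ev <- computeMAge(mixed, clock)
    mixedR2 <- stats::cor(ev$mage, sampleMetadata(mixed)$age)^2
    pur <- generatePurifiedCohorts(fx$reference, fx$driftModel,
                                   nPerType = nPerType,
                                   seed = deriveSeed(seed, 5500 + r))
    pe <- evaluatePurified(pur, fx$clocks)
    stat <- pe$stats[pe$stats$clock == clock@name, ]
    drops[r] <- mixedR2 - mean(stat$r2)
    ee <- stats::aggregate(eaa_pooled ~ cell + clock, pe$eaa, mean)
    lower <- vapply(unique(ee$clock), function(ck)
      ee$eaa_pooled[ee$cell == "CD8nv" & ee$clock == ck] <
        ee$eaa_pooled[ee$cell == "CD8mem" & ee$clock == ck], logical(1))
    if (all(lower)) cd8ok <- cd8ok + 1L
  }
  list(minR2Drop = min(drops), meanR2Drop = mean(drops),
       cd8OrderingReps = cd8ok, nReps = nReps)
}
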