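#' Generate a planted synthetic clock
#'
#' Builds a sparse linear clock whose variance is split, in a known
#' proportion, between an intrinsic component (weights on the shared
#' age-drift CpGs) and an extrinsic component (weights on cell-type marker
#' CpGs, i.e. a pure function of composition). The drift weights are
#' chosen so the intrinsic score equals the intrinsic age signal up to an
#' additive constant; the marker weights realise a chosen per-cell loading
#' vector gamma (so the extrinsic score equals \code{gamma' w} for mixing
#' proportions \code{w}). Both components are standardised on a noiseless
#' probe cohort so that on probe-like data
#' \code{Var(intrinsic) / (Var(intrinsic) + Var(extrinsic)) =
#' intrinsicFraction}.
#'
#' The default gamma is the naive-to-memory lymphocyte axis dominated by
#' the CD8 compartment (CD8mem +1, CD8nv -1, the B and CD4 naive/memory
#' subsets at +/-0.4, granulocytes +0.1), mimicking clocks trained on
#' age-correlated blood composition in which memory CD8 T cells are the
#' strongest extrinsic driver; \code{targetNoiseSd} adds per-cell jitter
#' so a panel of clocks differs in its cell loadings.
#'
#' @param reference A \linkS4class{ReferenceLibrary}.
#' @param driftModel A \linkS4class{DriftModel} (required unless
#'   \code{intrinsicFraction} is 0).
#' @param family "age_scale", "pace_scale" or "mitotic_scale".
#' @param intrinsicFraction Planted intrinsic variance share in [0, 1].
#' @param targetNoiseSd SD of the jitter added to the unit-scaled cell
#'   loading vector.
#' @param cellLoadings Optional named per-cell loading vector gamma
#'   replacing \code{defaultCellLoadings()} (e.g. a neutrophil-heavy
#'   loading for an inflammation-sensitive pace clock).
#' @param composition CompositionModel used for the probe cohort.
#' @param probeN Probe cohort size used to standardise the components.
#' @param intrinsicSd Between-subject intrinsic SD of the probe cohort.
#' @param name Clock name.
#' @param seed Integer seed.
#' @return A \linkS4class{ClockDefinition}.
#' @examples
#' ref <- generateReferenceLibrary(3, delta = 0.4, seed = 1)
#' dm <- makeDriftModel(seed = 1)
#' generateClock(ref, dm, intrinsicFraction = 0.5, seed = 3)
#' @export
generateClock <- function(reference, driftModel = NULL,
                          family = c("age_scale", "pace_scale",
                                     "mitotic_scale"),
                          intrinsicFraction = 0.5, targetNoiseSd = 0,
                          cellLoadings = NULL,
                          composition = bloodCompositionModel(),
                          probeN = 3000, intrinsicSd = 7,
                          name = NULL, seed = 1) {
  family <- match.arg(family)
  f <- intrinsicFraction
  if (f < 0 || f > 1) stop("intrinsicFraction must lie in [0, 1]")
  noDrift <- is.null(driftModel) || !length(driftModel@cpgIds)
  if (f > 0 && noDrift)
    stop("intrinsicFraction > 0 requires a non-empty drift panel")
  if (is.null(name))
    name <- sprintf("%s_f%02d", sub("_scale", "Clock", family),
                    round(100 * f))
  R <- meanBeta(reference)

  withSeed(seed, {
    gamma <- if (is.null(cellLoadings)) unname(defaultCellLoadings())
             else unname(cellLoadings[cellTypes12()])
    if (targetNoiseSd > 0)
      gamma <- gamma + stats::rnorm(12, 0, targetNoiseSd)
    ## marker weights realising gamma: R %*% v = gamma (R full row rank)
    v <- drop(crossprod(R, solve(tcrossprod(R), gamma)))
    names(v) <- colnames(R)

    ## probe cohort: noiseless, paired generator
    probe <- generateCohort(probeN, composition, reference,
                            driftModel = if (noDrift) makeDriftModel(seed = 99)
                                         else driftModel,
                            noisePrecision = Inf, intrinsicSd = intrinsicSd,
                            seed = deriveSeed(seed, 7))
    sc <- drop(trueProportions(probe) %*% gamma)
    gC <- if (f < 1) {
      if (sdSafe(sc) == 0)
        stop("extrinsic component has zero variance on the probe cohort")
      sqrt(1 - f) / sdSafe(sc)
    } else 0

    gD <- 0
    a <- numeric(0)
    if (!noDrift && f > 0) {
      a <- 1 / (length(driftModel@slope) * driftModel@slope)
      names(a) <- driftModel@cpgIds
      sd_ <- drop(t(betaMatrix(probe)[driftModel@cpgIds, , drop = FALSE]) %*% a)
      gD <- sqrt(f) / sdSafe(sd_)
    }

    ## family-specific reporting scale
    target <- switch(family,
      age_scale = c(mean(sampleMetadata(probe)$age),
                    stats::sd(sampleMetadata(probe)$age)),
      pace_scale = c(1, 0.15),
      mitotic_scale = c(3300, 1100))
    zProbe <- numeric(probeN)
    if (gD != 0)
      zProbe <- zProbe + gD *
        drop(t(betaMatrix(probe)[driftModel@cpgIds, , drop = FALSE]) %*% a)
    if (gC != 0) zProbe <- zProbe + gC * sc
    scale <- target[2] / sdSafe(zProbe)
    w <- c(if (gD != 0) scale * gD * a,
           if (gC != 0) scale * gC * v)
    w <- w[w != 0]
    new("ClockDefinition", name = name, family = family, weights = w,
        intercept = target[1] - scale * mean(zProbe),
        calibration = list(type = "identity"),
        intrinsicFraction = f)
  })
}

#' Default clock cell loadings
#'
#' The naive-to-memory lymphocyte axis dominated by the CD8 compartment
#' (CD8mem +1, CD8nv -1, B/CD4 naive and memory subsets at +/-0.4) with a
#' mild uniform granulocyte loading (+0.1): the per-cell extrinsic loading pattern
#' of a typical blood clock trained on age-correlated composition.
#'
#' @return Named numeric vector of length 12.
#' @export
defaultCellLoadings <- function() {
  g <- stats::setNames(numeric(12), cellTypes12())
  g[c("CD8mem", "CD8nv")] <- c(1, -1)
  g[c("Bmem", "CD4mem")] <- 0.4
  g[c("Bnv", "CD4nv")] <- -0.4
  g[c("Neu", "Eos", "Bas")] <- 0.1   # uniform granulocyte loading
  g
}

#' Generate the default six-clock panel
#'
#' Six planted clocks spanning the clock families studied in blood: four
#' age-scale clocks with decreasing intrinsic fractions, one pace-scale
#' and one mitotic-scale clock that are composition-dominated.
#'
#' @inheritParams generateClock
#' @return Named list of six \linkS4class{ClockDefinition} objects.
#' @export
generateClockPanel <- function(reference, driftModel,
                               composition = bloodCompositionModel(),
                               targetNoiseSd = 0.1, seed = 1) {
  spec <- list(
    ageClock1 = list(family = "age_scale", f = 0.75),
    ageClock2 = list(family = "age_scale", f = 0.55),
    ageClock3 = list(family = "age_scale", f = 0.45),
    ageClock4 = list(family = "age_scale", f = 0.35),
    paceClock = list(family = "pace_scale", f = 0.25),
    mitoticClock = list(family = "mitotic_scale", f = 0.15)
  )
  out <- lapply(seq_along(spec), function(i) {
    generateClock(reference, driftModel, family = spec[[i]]$family,
                  intrinsicFraction = spec[[i]]$f,
                  targetNoiseSd = targetNoiseSd,
                  composition = composition,
                  name = names(spec)[i], seed = deriveSeed(seed, 100 + i))
  })
  names(out) <- names(spec)
  out
}

#' Decompose a clock's variance into drift and marker components
#'
#' ANOVA-style split of the linear clock score on a cohort: the variance
#' of the partial score over drift CpGs versus over marker CpGs.
#' Covariance between the two components is excluded, so on a cohort
#' matching the probe conditions the drift share of a planted clock equals
#' its intrinsic fraction.
#'
#' @param clock A \linkS4class{ClockDefinition}.
#' @param cohort A \linkS4class{MethylCohort} with a rowData "kind"
#'   column (as produced by \code{\link{generateCohort}}).
#' @return List with \code{varDrift}, \code{varMarker}, \code{driftShare}.
#' @export
decomposeClockVariance <- function(clock, cohort) {
  kind <- SummarizedExperiment::rowData(cohort)$kind
  b <- betaMatrix(cohort)
  part <- function(sel) {
    ids <- intersect(names(clock@weights), rownames(b)[sel])
    if (!length(ids)) return(numeric(ncol(b)))
    drop(crossprod(b[ids, , drop = FALSE], clock@weights[ids]))
  }
  vd <- stats::var(part(kind == "drift"))
  vm <- stats::var(part(kind == "marker"))
  list(varDrift = vd, varMarker = vm, driftShare = vd / (vd + vm))
}
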