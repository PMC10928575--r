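#' Create an intrinsic drift-CpG panel
#'
#' Drift CpGs carry the cell-type-shared intrinsic aging signal: their
#' mean beta rises linearly with the intrinsic age signal at \code{slope}
#' beta units per year from a baseline drawn uniformly on
#' \code{baseRange}. Identifiers are disjoint from reference markers by
#' construction (distinct prefix).
#'
#' @param nCpgs Number of drift CpGs.
#' @param slope Beta change per year (scalar or per-CpG).
#' @param baseRange Range of baseline betas.
#' @param seed Integer seed.
#' @return A \linkS4class{DriftModel}.
#' @export
makeDriftModel <- function(nCpgs = 20, slope = 3e-4,
                           baseRange = c(0.25, 0.55), seed = 1) {
  withSeed(seed, {
    new("DriftModel",
        cpgIds = sprintf("cgD%04d", seq_len(nCpgs)),
        base = stats::runif(nCpgs, baseRange[1], baseRange[2]),
        slope = rep_len(slope, nCpgs))
  })
}

#' Generate a synthetic blood methylation cohort
#'
#' Mixes reference cell-type signatures with per-sample true proportions
#' drawn from a \linkS4class{CompositionModel}, adds an intrinsic
#' age-drift panel shared across cell types, and observes every CpG
#' through Beta noise: \code{beta ~ Beta(mu, precision)} with
#' \code{var = mu(1-mu)/(1+precision)}. On marker CpGs
#' \code{mu = w' R}; on drift CpGs \code{mu = base + slope * s} (clipped
#' to [0,1]) where the intrinsic signal \code{s = age +
#' N(0, intrinsicSd) + diseaseDriftYears * diseased}.
#'
#' @param n Number of samples (ignored when \code{metadata} is supplied).
#' @param composition A \linkS4class{CompositionModel}.
#' @param reference A \linkS4class{ReferenceLibrary}.
#' @param driftModel A \linkS4class{DriftModel}; built from
#'   \code{nDriftCpgs}/\code{driftSlope} when NULL.
#' @param nDriftCpgs,driftSlope Drift panel size and per-year beta slope
#'   used when \code{driftModel} is NULL.
#' @param noisePrecision Beta-noise concentration; \code{Inf} = noiseless.
#' @param intrinsicSd Between-subject SD (years) of the intrinsic age
#'   signal around chronological age.
#' @param diseaseDriftYears Years added to the intrinsic signal of
#'   diseased samples (a planted direct, composition-free disease effect).
#' @param metadata Optional metadata data.frame (see
#'   \code{\link{simulateSampleMetadata}}); simulated when NULL.
#' @param diseasePrev,newbornFrac Passed to the metadata simulator.
#' @param seed Integer seed; output is deterministic given it.
#' @return A \linkS4class{MethylCohort} with truth slots filled.
#' @examples
#' ref <- generateReferenceLibrary(3, delta = 0.4, seed = 1)
#' ch <- generateCohort(25, bloodCompositionModel(), ref, seed = 2)
#' ch
#' @export
generateCohort <- function(n, composition, reference, driftModel = NULL,
                           nDriftCpgs = 20, driftSlope = 3e-4,
                           noisePrecision = 100, intrinsicSd = 7,
                           diseaseDriftYears = 0, metadata = NULL,
                           diseasePrev = 0, newbornFrac = 0.1, seed = 1) {
  stopifnot(is(reference, "ReferenceLibrary"))
  if (is.null(metadata))
    metadata <- simulateSampleMetadata(n, seed = deriveSeed(seed, 1),
                                       diseasePrev = diseasePrev,
                                       newbornFrac = newbornFrac)
  n <- nrow(metadata)
  if (n < 1L) stop("need at least one sample")
  if (is.null(driftModel))
    driftModel <- makeDriftModel(nDriftCpgs, driftSlope,
                                 seed = deriveSeed(seed, 2))
  if (length(intersect(driftModel@cpgIds, markerCpGs(reference))))
    stop("drift CpGs must be disjoint from reference marker CpGs")

  W <- sampleComposition(composition, metadata, seed = deriveSeed(seed, 3))
  R <- meanBeta(reference)
  muMarker <- W %*% R
  if (min(muMarker) < -1e-9 || max(muMarker) > 1 + 1e-9)
    stop("internal consistency error: mixture means outside [0, 1]")

  withSeed(deriveSeed(seed, 4), {
    diseased <- as.numeric(metadata$disease != "none")
    s <- metadata$age + diseaseDriftYears * diseased
    if (intrinsicSd > 0) s <- s + stats::rnorm(n, 0, intrinsicSd)
    muDrift <- outer(s, driftModel@slope) +
      matrix(rep(driftModel@base, each = n), n)
    muDrift <- pmin(pmax(muDrift, 0), 1)
    colnames(muDrift) <- driftModel@cpgIds
    mu <- cbind(muMarker, muDrift)
    beta <- matrix(rbetaMeanPrec(length(mu), as.vector(mu), noisePrecision),
                   nrow = n, dimnames = dimnames(mu))
    rd <- S4Vectors::DataFrame(
      kind = rep(c("marker", "drift"), c(ncol(muMarker), ncol(muDrift))),
      row.names = colnames(mu))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(beta = t(beta)),
      colData = S4Vectors::DataFrame(metadata, row.names = metadata$sample_id),
      rowData = rd)
    out <- new("MethylCohort", se, trueProportions = W,
               trueIntrinsicSignal = s)
    S4Vectors::metadata(out)$driftModel <- driftModel
    S4Vectors::metadata(out)$noisePrecision <- noisePrecision
    out
  })
}

#' Generate purified-cell cohorts
#'
#' One small cohort per cell type in which every sample is a pure
#' population (true proportion vector equal to a unit vector), emulating
#' clock evaluation panels of flow-sorted leukocytes from adult donors.
#'
#' @inheritParams generateCohort
#' @param nPerType Samples per cell type.
#' @param ageRange Donor age range (years).
#' @return Named list of \linkS4class{MethylCohort}, one per cell type.
#' @export
generatePurifiedCohorts <- function(reference, driftModel = NULL,
                                    nPerType = 40, ageRange = c(20, 70),
                                    noisePrecision = 100, intrinsicSd = 7,
                                    seed = 1) {
  if (is.null(driftModel))
    driftModel <- makeDriftModel(seed = deriveSeed(seed, 2))
  cells <- cellTypes12()
  out <- vector("list", length(cells))
  names(out) <- cells
  for (i in seq_along(cells)) {
    ## composition point mass at cell i via extreme fixed logits
    logits <- stats::setNames(rep(-60, 12), cells)
    logits[cells[i]] <- 0
    pure <- newCompositionModel(logits, dispersion = 0)
    md <- simulateSampleMetadata(nPerType, seed = deriveSeed(seed, 10 + i),
                                 newbornFrac = 0, ageRange = ageRange,
                                 idPrefix = paste0(cells[i], "_"))
    ch <- generateCohort(nPerType, pure, reference, driftModel = driftModel,
                         noisePrecision = noisePrecision,
                         intrinsicSd = intrinsicSd, metadata = md,
                         seed = deriveSeed(seed, 40 + i))
    ## exact unit rows (softmax of the extreme logits is 1 to machine precision)
    tp <- matrix(0, nPerType, 12, dimnames = list(md$sample_id, cells))
    tp[, cells[i]] <- 1
    ch@trueProportions <- tp
    out[[i]] <- ch
  }
  out
}
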