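#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ReferenceLibrary: cell-type methylation signatures
#'
#' Mean beta values of marker CpGs in purified leukocyte populations,
#' used both to simulate mixtures and to deconvolve them. Rows are the 12
#' canonical cell types, columns are marker CpGs.
#'
#' @slot cellTypes Character vector of cell-type labels (rows of
#'   \code{meanBeta}).
#' @slot meanBeta Numeric matrix (cell types x marker CpGs) of mean beta
#'   values in [0, 1].
#' @slot precision Positive scalar or per-CpG vector; concentration of the
#'   Beta observation noise around \code{meanBeta} when simulating.
#' @slot markerType Character vector (one per CpG) naming the cell type a
#'   marker discriminates, or NA when unknown (user-supplied libraries).
#' @export
setClass("ReferenceLibrary",
  representation(
    cellTypes = "character",
    meanBeta = "matrix",
    precision = "numeric",
    markerType = "character"
  )
)

setValidity("ReferenceLibrary", function(object) {
  msg <- character()
  m <- object@meanBeta
  if (anyDuplicated(object@cellTypes))
    msg <- c(msg, "duplicated cell-type labels")
  if (!identical(rownames(m), object@cellTypes))
    msg <- c(msg, "rownames(meanBeta) must equal cellTypes")
  if (is.null(colnames(m)))
    msg <- c(msg, "meanBeta must have CpG column names")
  if (any(m < 0 | m > 1))
    msg <- c(msg, "meanBeta values must lie in [0, 1]")
  if (any(object@precision <= 0))
    msg <- c(msg, "precision must be positive")
  if (length(object@markerType) &&
      length(object@markerType) != ncol(m))
    msg <- c(msg, "markerType must have one entry per CpG")
  if (nrow(m) >= 2L && qr(m)$rank < nrow(m))
    msg <- c(msg, "meanBeta must have full row rank")
  if (length(msg)) msg else TRUE
})

#' CompositionModel: logistic-normal immune composition generator
#'
#' Cell-type proportions are softmax-transformed Gaussian logits:
#' \code{logit_k = baseline_k + slope_k * min(age, knot_k) +
#' diseaseShift_k * diseased + N(0, dispersion)}. Additive logit effects
#' give independent control over per-cell age trends and disease shifts,
#' which is exactly the structure the downstream association models are
#' asked to recover.
#'
#' @slot baselineLogits Named numeric vector, length 12.
#' @slot ageSlopes Per-year logit change, length 12.
#' @slot ageKnots Age (years) after which a cell's age trend plateaus;
#'   Inf for a linear trend over the whole range.
#' @slot diseaseShifts Logit shift applied when a sample is diseased.
#' @slot dispersion Non-negative between-subject logit SD (independent
#'   per-cell component).
#' @slot axisLoadings Loadings of a shared between-subject logit factor
#'   (the antigen-experience axis: memory compartments co-move up while
#'   naive compartments move down); length 12.
#' @slot axisSd SD of the shared factor (0 disables it).
#' @slot newbornOverrides Optional logit vector replacing the baseline at
#'   age exactly 0 (e.g. a nucleated-RBC/basophil contamination analogue);
#'   length 0 disables the override.
#' @export
setClass("CompositionModel",
  representation(
    baselineLogits = "numeric",
    ageSlopes = "numeric",
    ageKnots = "numeric",
    diseaseShifts = "numeric",
    dispersion = "numeric",
    axisLoadings = "numeric",
    axisSd = "numeric",
    newbornOverrides = "numeric"
  )
)

setValidity("CompositionModel", function(object) {
  msg <- character()
  k <- length(cellTypes12())
  if (length(object@baselineLogits) != k ||
      !identical(names(object@baselineLogits), cellTypes12()))
    msg <- c(msg, "baselineLogits must be named by the 12 canonical cell types")
  for (s in c("ageSlopes", "ageKnots", "diseaseShifts", "axisLoadings"))
    if (length(slot(object, s)) != k)
      msg <- c(msg, sprintf("%s must have length 12", s))
  if (length(object@dispersion) != 1L || object@dispersion < 0)
    msg <- c(msg, "dispersion must be a non-negative scalar")
  if (length(object@axisSd) != 1L || object@axisSd < 0)
    msg <- c(msg, "axisSd must be a non-negative scalar")
  if (length(object@newbornOverrides) &&
      length(object@newbornOverrides) != k)
    msg <- c(msg, "newbornOverrides must have length 0 or 12")
  if (length(msg)) msg else TRUE
})

#' DriftModel: intrinsic age-drift CpG panel
#'
#' CpGs whose methylation drifts linearly with an intrinsic age signal,
#' shared across cell types. \code{mu = base + slope * signal}, clipped to
#' [0, 1]; the intrinsic signal is chronological age plus between-subject
#' deviation (and, in disease scenarios, a planted disease offset).
#'
#' @slot cpgIds Character CpG identifiers (disjoint from reference markers).
#' @slot base Baseline beta per CpG.
#' @slot slope Beta change per year of intrinsic signal, per CpG.
#' @export
setClass("DriftModel",
  representation(cpgIds = "character", base = "numeric", slope = "numeric")
)

setValidity("DriftModel", function(object) {
  n <- length(object@cpgIds)
  msg <- character()
  if (length(object@base) != n || length(object@slope) != n)
    msg <- c(msg, "base and slope must match cpgIds in length")
  if (anyDuplicated(object@cpgIds)) msg <- c(msg, "duplicated drift CpG ids")
  if (n && any(object@base < 0 | object@base > 1))
    msg <- c(msg, "base beta must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ClockDefinition: sparse linear methylation clock
#'
#' A linear predictor over CpG beta values with an intercept and a
#' monotone calibration transform. Families: \code{age_scale} reports
#' years, \code{pace_scale} a unitless aging pace, \code{mitotic_scale}
#' cumulative stem-cell division counts.
#'
#' @slot name Clock name.
#' @slot family One of "age_scale", "pace_scale", "mitotic_scale".
#' @slot weights Named numeric vector of CpG weights (sparse; only
#'   non-zero entries are stored).
#' @slot intercept Scalar intercept of the linear score.
#' @slot calibration List with element \code{type} ("identity" or
#'   "log_linear") and, for log_linear, \code{adult_age}.
#' @slot intrinsicFraction For planted synthetic clocks, the share of the
#'   clock's variance carried by intrinsic drift CpGs (NA for
#'   user-supplied clocks).
#' @export
setClass("ClockDefinition",
  representation(
    name = "character",
    family = "character",
    weights = "numeric",
    intercept = "numeric",
    calibration = "list",
    intrinsicFraction = "numeric"
  )
)

setValidity("ClockDefinition", function(object) {
  msg <- character()
  if (!object@family %in% c("age_scale", "pace_scale", "mitotic_scale"))
    msg <- c(msg, "unknown clock family")
  if (!length(object@weights) || is.null(names(object@weights)) ||
      all(object@weights == 0))
    msg <- c(msg, "clock needs at least one non-zero named weight")
  if (!object@calibration$type %in% c("identity", "log_linear"))
    msg <- c(msg, "calibration type must be identity or log_linear")
  if (identical(object@calibration$type, "log_linear") &&
      is.null(object@calibration$adult_age))
    msg <- c(msg, "log_linear calibration requires adult_age")
  f <- object@intrinsicFraction
  if (length(f) == 1L && !is.na(f) && (f < 0 || f > 1))
    msg <- c(msg, "intrinsicFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MethylCohort: beta matrix plus sample metadata
#'
#' A \linkS4class{SummarizedExperiment} with one assay \code{"beta"}
#' (CpGs x samples, values in [0, 1]) and sample metadata in
#' \code{colData} (age, sex, ancestry, disease, batch). Synthetic cohorts
#' additionally record the true mixing proportions and the true intrinsic
#' age signal used by the generator, so downstream estimates can be scored
#' against ground truth.
#'
#' @slot trueProportions Samples x 12 matrix on the simplex (0-row when
#'   unknown, i.e. for real data).
#' @slot trueIntrinsicSignal Per-sample intrinsic age signal in years
#'   (length 0 when unknown).
#' @export
setClass("MethylCohort",
  contains = "SummarizedExperiment",
  representation(
    trueProportions = "matrix",
    trueIntrinsicSignal = "numeric"
  )
)

setValidity("MethylCohort", function(object) {
  msg <- character()
  b <- SummarizedExperiment::assay(object, "beta")
  if (any(b < 0 | b > 1, na.rm = TRUE))
    msg <- c(msg, "beta values must lie in [0, 1]")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "age", "sex", "ancestry", "disease")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(cd$sample_id)) msg <- c(msg, "sample_ids must be unique")
    if (any(cd$age < 0 | cd$age > 99))
      msg <- c(msg, "ages must lie in [0, 99]")
  }
  tp <- object@trueProportions
  if (nrow(tp)) {
    if (nrow(tp) != ncol(object))
      msg <- c(msg, "trueProportions must have one row per sample")
    if (max(abs(rowSums(tp) - 1)) > 1e-12 || any(tp < 0))
      msg <- c(msg, "trueProportions rows must lie on the simplex")
  }
  if (length(object@trueIntrinsicSignal) &&
      length(object@trueIntrinsicSignal) != ncol(object))
    msg <- c(msg, "trueIntrinsicSignal must have one value per sample")
  if (length(msg)) msg else TRUE
})

#' CellProportions: deconvolution estimates
#'
#' Estimated cell-type proportions per sample, with the per-sample
#' root-mean-square fit residual and the QC mask. Masked samples carry NA
#' proportions.
#'
#' @slot proportions Samples x 12 matrix; unmasked rows are componentwise
#'   non-negative and sum to at most 1 (exactly 1 under the eq_one
#'   constraint).
#' @slot fitResidual Per-sample RMS residual over the marker CpGs used.
#' @slot masked Logical per sample; TRUE when more than the allowed
#'   fraction of library CpGs was missing.
#' @slot constraint "le_one" or "eq_one".
#' @export
setClass("CellProportions",
  representation(
    proportions = "matrix",
    fitResidual = "numeric",
    masked = "logical",
    constraint = "character"
  )
)

setValidity("CellProportions", function(object) {
  msg <- character()
  p <- object@proportions
  n <- nrow(p)
  if (length(object@fitResidual) != n || length(object@masked) != n)
    msg <- c(msg, "fitResidual and masked must have one entry per sample")
  ok <- !object@masked
  if (any(ok)) {
    pu <- p[ok, , drop = FALSE]
    if (any(is.na(pu)))
      msg <- c(msg, "unmasked rows must be complete")
    else {
      if (min(pu) < -1e-8) msg <- c(msg, "proportions must be non-negative")
      if (max(rowSums(pu)) > 1 + 1e-8)
        msg <- c(msg, "row sums must not exceed 1")
    }
  }
  if (any(object@masked) && !all(is.na(p[object@masked, , drop = FALSE])))
    msg <- c(msg, "masked rows must be all-NA")
  if (length(msg)) msg else TRUE
})
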