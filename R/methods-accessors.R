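#' @rdname ReferenceLibrary-class
#' @export
setMethod("cellTypes", "ReferenceLibrary", function(x) x@cellTypes)

#' @rdname ReferenceLibrary-class
#' @export
setMethod("meanBeta", "ReferenceLibrary", function(x) x@meanBeta)

#' @rdname ReferenceLibrary-class
#' @export
setMethod("markerCpGs", "ReferenceLibrary", function(x) colnames(x@meanBeta))

#' @rdname ReferenceLibrary-class
#' @export
setMethod("show", "ReferenceLibrary", function(object) {
  cat("ReferenceLibrary:", nrow(object@meanBeta), "cell types x",
      ncol(object@meanBeta), "marker CpGs\n")
  cat("  cell types:", paste(object@cellTypes, collapse = ", "), "\n")
  cat("  beta range: [", round(min(object@meanBeta), 3), ",",
      round(max(object@meanBeta), 3), "]\n")
})

#' @rdname DriftModel-class
#' @param x,object An object.
#' @export
setMethod("markerCpGs", "DriftModel", function(x) x@cpgIds)

#' @rdname DriftModel-class
#' @export
setMethod("show", "DriftModel", function(object) {
  cat("DriftModel:", length(object@cpgIds), "intrinsic drift CpGs;",
      "slope range [", signif(min(object@slope), 3), ",",
      signif(max(object@slope), 3), "] beta/yr\n")
})

#' @rdname CompositionModel-class
#' @param object A CompositionModel.
#' @export
setMethod("show", "CompositionModel", function(object) {
  cat("CompositionModel (logistic-normal, 12 cell types)\n")
  cat("  dispersion:", object@dispersion, "| newborn override:",
      if (length(object@newbornOverrides)) "on" else "off", "\n")
  trending <- cellTypes12()[object@ageSlopes != 0]
  if (length(trending))
    cat("  age-trending cells:", paste(trending, collapse = ", "), "\n")
})

#' @rdname ClockDefinition-class
#' @param object A ClockDefinition.
#' @export
setMethod("show", "ClockDefinition", function(object) {
  cat(sprintf("ClockDefinition '%s' (%s): %d CpGs, intercept %.3g\n",
              object@name, object@family, length(object@weights),
              object@intercept))
  cat("  calibration:", object@calibration$type)
  if (!is.na(object@intrinsicFraction))
    cat(" | planted intrinsic fraction:", object@intrinsicFraction)
  cat("\n")
})

#' @rdname MethylCohort-class
#' @export
setMethod("betaMatrix", "MethylCohort", function(x)
  SummarizedExperiment::assay(x, "beta"))

#' @rdname MethylCohort-class
#' @export
setMethod("sampleMetadata", "MethylCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname MethylCohort-class
#' @export
setMethod("trueProportions", "MethylCohort", function(x) {
  if (!nrow(x@trueProportions)) NULL else x@trueProportions
})

#' @rdname MethylCohort-class
#' @export
setMethod("trueIntrinsicSignal", "MethylCohort", function(x) {
  if (!length(x@trueIntrinsicSignal)) NULL else x@trueIntrinsicSignal
})

#' @rdname MethylCohort-class
#' @export
setMethod("show", "MethylCohort", function(object) {
  callNextMethod()
  cat("truth:",
      if (nrow(object@trueProportions)) "proportions" else "-",
      "|",
      if (length(object@trueIntrinsicSignal)) "intrinsic signal" else "-",
      "\n")
})

#' @rdname CellProportions-class
#' @param x,object A CellProportions object.
#' @param percent Return proportions on the 0-100 scale.
#' @param ... Unused.
#' @export
setMethod("proportions", "CellProportions", function(x, percent = FALSE, ...) {
  if (percent) x@proportions * 100 else x@proportions
})

#' @rdname CellProportions-class
#' @export
setMethod("fitResidual", "CellProportions", function(x) x@fitResidual)

#' @rdname CellProportions-class
#' @export
setMethod("maskedSamples", "CellProportions", function(x) x@masked)

#' @rdname CellProportions-class
#' @export
setMethod("show", "CellProportions", function(object) {
  cat("CellProportions:", nrow(object@proportions), "samples,",
      sum(object@masked), "masked; constraint:", object@constraint, "\n")
  if (any(!object@masked))
    cat("  mean RMS residual (unmasked):",
        signif(mean(object@fitResidual[!object@masked]), 4), "\n")
})
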