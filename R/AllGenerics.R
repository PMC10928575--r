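#' @rdname ReferenceLibrary-class
#' @param x,object An object.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname ReferenceLibrary-class
#' @export
setGeneric("meanBeta", function(x) standardGeneric("meanBeta"))

#' @rdname ReferenceLibrary-class
#' @export
setGeneric("markerCpGs", function(x) standardGeneric("markerCpGs"))

#' @rdname MethylCohort-class
#' @export
setGeneric("betaMatrix", function(x) standardGeneric("betaMatrix"))

#' @rdname MethylCohort-class
#' @export
setGeneric("sampleMetadata", function(x) standardGeneric("sampleMetadata"))

#' @rdname MethylCohort-class
#' @export
setGeneric("trueProportions", function(x) standardGeneric("trueProportions"))

#' @rdname MethylCohort-class
#' @export
setGeneric("trueIntrinsicSignal",
  function(x) standardGeneric("trueIntrinsicSignal"))

#' @rdname CellProportions-class
#' @export
setGeneric("proportions", function(x, ...) standardGeneric("proportions"))

#' @rdname CellProportions-class
#' @export
setGeneric("fitResidual", function(x) standardGeneric("fitResidual"))

#' @rdname CellProportions-class
#' @export
setGeneric("maskedSamples", function(x) standardGeneric("maskedSamples"))

#' @rdname estimateProportions
#' @export
setGeneric("estimateProportions",
  function(beta, reference, ...) standardGeneric("estimateProportions"))

#' @rdname computeMAge
#' @export
setGeneric("computeMAge",
  function(cohort, clock, ...) standardGeneric("computeMAge"))
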