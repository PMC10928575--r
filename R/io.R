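#' Read and write the pipeline's delimited formats
#'
#' All tabular artifacts are headered CSV. Beta matrices are written with
#' samples as rows and CpG identifiers as the header; reference libraries
#' with cell types as rows. Clock definitions and scenarios are JSON.
#'
#' @param path File path.
#' @param beta Samples x CpGs matrix.
#' @name immunoEAA-io
NULL

#' @rdname immunoEAA-io
#' @export
writeBetaCsv <- function(beta, path) {
  df <- data.frame(sample_id = rownames(beta), beta, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname immunoEAA-io
#' @export
readBetaCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname immunoEAA-io
#' @param reference A \linkS4class{ReferenceLibrary}.
#' @export
writeReferenceCsv <- function(reference, path) {
  df <- data.frame(cell_type = cellTypes(reference), meanBeta(reference),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname immunoEAA-io
#' @param precision Simulation precision attached on read.
#' @export
readReferenceCsv <- function(path, precision = 100) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new("ReferenceLibrary", cellTypes = rownames(m), meanBeta = m,
      precision = precision, markerType = character(0))
}

#' @rdname immunoEAA-io
#' @param clock A \linkS4class{ClockDefinition}.
#' @export
writeClockJson <- function(clock, path) {
  obj <- list(name = clock@name, family = clock@family,
              calibration = clock@calibration,
              intercept = clock@intercept,
              weights = as.list(clock@weights))
  if (!is.na(clock@intrinsicFraction))
    obj$intrinsic_fraction <- clock@intrinsicFraction
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname immunoEAA-io
#' @export
readClockJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ClockDefinition", name = obj$name, family = obj$family,
      weights = unlist(obj$weights),
      intercept = obj$intercept,
      calibration = as.list(obj$calibration),
      intrinsicFraction = if (is.null(obj$intrinsic_fraction)) NA_real_
                          else obj$intrinsic_fraction)
}

#' Default simulation scenario
#'
#' The versioned study conditions used throughout: the blood-aging
#' composition model (dispersion 0.7), disease prevalence, a 20-CpG drift
#' panel at 3e-4 beta/yr, intrinsic between-subject SD of 7 years, Beta
#' observation precision 100, and n = 2000. The two planted disease
#' mechanisms are controlled by \code{diseaseShifts} (composition-mediated)
#' and \code{diseaseDriftYears} (direct intrinsic effect).
#'
#' @param name Scenario name.
#' @param n Cohort size.
#' @param diseasePrev Disease prevalence.
#' @param diseaseDriftYears Direct intrinsic disease effect (years).
#' @param compositionDisease Keep the composition-mediated disease shifts
#'   (set FALSE for an intrinsic-only disease scenario).
#' @param dispersion Between-subject logit SD.
#' @param noisePrecision Beta noise precision.
#' @return Scenario list (serialisable with \code{writeScenarioJson}).
#' @export
defaultScenario <- function(name = "bloodAging", n = 2000,
                            diseasePrev = 0, diseaseDriftYears = 0,
                            compositionDisease = TRUE, dispersion = 0.7,
                            noisePrecision = 100) {
  cm <- bloodCompositionModel(dispersion = dispersion)
  shifts <- if (compositionDisease) cm@diseaseShifts else numeric(12)
  list(
    name = name,
    composition = list(
      baselineLogits = as.list(cm@baselineLogits),
      ageSlopes = cm@ageSlopes,
      ageKnots = pmin(cm@ageKnots, 999),   # JSON-safe stand-in for Inf

      diseaseShifts = shifts,
      dispersion = cm@dispersion,
      axisLoadings = cm@axisLoadings,
      axisSd = cm@axisSd,
      newbornOverrides = cm@newbornOverrides
    ),
    nCpgsPerType = 12, refDelta = 0.35,
    nDriftCpgs = 20, driftSlope = 3e-4, intrinsicSd = 7,
    noisePrecision = noisePrecision, n = n,
    diseasePrev = diseasePrev, newbornFrac = 0.1,
    diseaseDriftYears = diseaseDriftYears
  )
}

#' @rdname immunoEAA-io
#' @param scenario Scenario list.
#' @export
writeScenarioJson <- function(scenario, path) {
  jsonlite::write_json(scenario, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname immunoEAA-io
#' @export
readScenarioJson <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc$composition$baselineLogits <- unlist(sc$composition$baselineLogits)
  sc
}

#' Composition model from a scenario
#'
#' @param scenario Scenario list (see \code{\link{defaultScenario}}).
#' @return A \linkS4class{CompositionModel}.
#' @export
scenarioComposition <- function(scenario) {
  cm <- scenario$composition
  knots <- cm$ageKnots
  knots[is.na(knots)] <- Inf   # JSON serialises Inf as null/NA
  newCompositionModel(unlist(cm$baselineLogits),
                      ageSlopes = cm$ageSlopes, ageKnots = knots,
                      diseaseShifts = cm$diseaseShifts,
                      dispersion = cm$dispersion,
                      axisLoadings = if (length(cm$axisLoadings))
                        cm$axisLoadings else numeric(12),
                      axisSd = if (is.null(cm$axisSd)) 0 else cm$axisSd,
                      newbornOverrides =
                        if (length(cm$newbornOverrides))
                          cm$newbornOverrides else numeric(0))
}

#' Generate a cohort directly from a scenario
#'
#' @param scenario Scenario list.
#' @param reference A \linkS4class{ReferenceLibrary} (generated from the
#'   scenario when NULL).
#' @param driftModel A \linkS4class{DriftModel} (generated when NULL).
#' @param seed Integer seed.
#' @param n Override the scenario's cohort size.
#' @return A \linkS4class{MethylCohort}.
#' @export
scenarioCohort <- function(scenario, reference = NULL, driftModel = NULL,
                           seed = 1, n = NULL) {
  if (is.null(reference))
    reference <- generateReferenceLibrary(scenario$nCpgsPerType,
                                          delta = scenario$refDelta,
                                          precision = scenario$noisePrecision,
                                          seed = deriveSeed(seed, 900))
  if (is.null(driftModel))
    driftModel <- makeDriftModel(scenario$nDriftCpgs, scenario$driftSlope,
                                 seed = deriveSeed(seed, 901))
  generateCohort(if (is.null(n)) scenario$n else n,
                 scenarioComposition(scenario), reference,
                 driftModel = driftModel,
                 noisePrecision = scenario$noisePrecision,
                 intrinsicSd = scenario$intrinsicSd,
                 diseaseDriftYears = scenario$diseaseDriftYears,
                 diseasePrev = scenario$diseasePrev,
                 newbornFrac = scenario$newbornFrac,
                 seed = seed)
}
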