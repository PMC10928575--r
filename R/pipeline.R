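#' Pipeline stages in dependency order
#'
#' @return Character vector of stage names.
#' @export
pipelineStages <- function() {
  c("simulate", "deconvolve", "clocks", "associate", "decompose", "confound")
}

## upstream stages each stage's declared inputs come from
stageDeps <- list(
  simulate = character(0),
  deconvolve = "simulate",
  clocks = c("simulate", "deconvolve"),
  associate = c("simulate", "deconvolve", "clocks"),
  decompose = c("simulate", "deconvolve", "clocks"),
  confound = c("simulate", "deconvolve", "clocks")
)

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic
#' scenario: simulate (reference, drift panel, cohort, clock panel),
#' deconvolve, clocks (age-acceleration table), associate (association
#' grid), decompose (partial/additional R-squared and composition PCA)
#' and confound (case/control matching and effect grid; requires a
#' scenario with diseased samples). Every stage writes headered CSV (or
#' JSON) artifacts into \code{outDir}, and a manifest records seeds,
#' artifact checksums and QC counts. Reruns with the same config are
#' byte-identical.
#'
#' @param config List with elements \code{scenario} (list, see
#'   \code{\link{defaultScenario}}, or path to a scenario JSON),
#'   \code{seed} (integer, mandatory: no wall-clock seeding), \code{n}
#'   (optional override), \code{outDir}, \code{stages} (subset of
#'   \code{pipelineStages()}), and optional \code{fdrFamily},
#'   \code{sumConstraint}, \code{caseLabel}.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$outDir))
  sc <- config$scenario
  if (is.character(sc)) sc <- readScenarioJson(sc)
  if (is.null(sc)) sc <- defaultScenario()
  stages <- if (is.null(config$stages)) pipelineStages() else config$stages
  stages <- pipelineStages()[pipelineStages() %in% stages]
  for (st in stages) {
    missingDeps <- setdiff(stageDeps[[st]], stages)
    if (length(missingDeps))
      stop("declared-input check failed: stage '", st,
           "' requires disabled stage(s): ",
           paste(missingDeps, collapse = ", "))
  }
  seed <- as.integer(config$seed)
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log_ <- list()
  artifacts <- character(0)
  note <- function(...) log_[[length(log_) + 1L]] <<- paste0(...)
  emit <- function(name) artifacts <<- c(artifacts, name)

  ## --- simulate -----------------------------------------------------
  ref <- generateReferenceLibrary(sc$nCpgsPerType, delta = sc$refDelta,
                                  precision = sc$noisePrecision,
                                  seed = deriveSeed(seed, 900))
  dm <- makeDriftModel(sc$nDriftCpgs, sc$driftSlope,
                       seed = deriveSeed(seed, 901))
  cohort <- scenarioCohort(sc, reference = ref, driftModel = dm,
                           seed = seed, n = config$n)
  clocks <- generateClockPanel(ref, dm, composition = scenarioComposition(sc),
                               seed = deriveSeed(seed, 902))
  md <- sampleMetadata(cohort)
  if ("simulate" %in% stages) {
    writeBetaCsv(t(betaMatrix(cohort)), file.path(outDir, "beta.csv"))
    utils::write.csv(md, file.path(outDir, "metadata.csv"),
                     row.names = FALSE)
    writeBetaCsv(trueProportions(cohort),
                 file.path(outDir, "true_proportions.csv"))
    writeReferenceCsv(ref, file.path(outDir, "reference.csv"))
    for (ck in clocks)
      writeClockJson(ck, file.path(outDir, paste0("clock_", ck@name, ".json")))
    writeScenarioJson(sc, file.path(outDir, "scenario.json"))
    emit(c("beta.csv", "metadata.csv", "true_proportions.csv",
           "reference.csv", "scenario.json",
           paste0("clock_", names(clocks), ".json")))
    note("simulate: n=", ncol(cohort), ", CpGs=", nrow(cohort))
  }

  props <- accel <- NULL
  if ("deconvolve" %in% stages) {
    props <- estimateProportions(cohort, ref,
      sumConstraint = if (is.null(config$sumConstraint)) "le_one"
                      else config$sumConstraint)
    writeBetaCsv(proportions(props), file.path(outDir, "proportions.csv"))
    emit("proportions.csv")
    note("deconvolve: masked=", sum(maskedSamples(props)))
  }
  if ("clocks" %in% stages) {
    accel <- ageAccelTable(cohort, clocks, props)
    utils::write.csv(accel, file.path(outDir, "age_acceleration.csv"),
                     row.names = FALSE)
    emit("age_acceleration.csv")
    note("clocks: masked rows=", sum(accel$masked))
  }
  if ("associate" %in% stages) {
    assoc <- runAssociationGrid(accel, props, md,
      fdrFamily = if (is.null(config$fdrFamily)) "per_clock_group"
                  else config$fdrFamily)
    utils::write.csv(assoc, file.path(outDir, "associations.csv"),
                     row.names = FALSE)
    emit("associations.csv")
    note("associate: rows=", nrow(assoc))
  }
  if ("decompose" %in% stages) {
    dec <- list()
    add <- list()
    for (clk in names(clocks)) {
      y <- accel$eaa_resid[accel$clock == clk]
      d <- decomposeEaaVariance(y, props, md)
      dec[[clk]] <- data.frame(clock = clk, block = names(d$partial),
                               partial_r2 = unname(d$partial))
      add[[clk]] <- data.frame(clock = clk, cell = names(d$additional),
                               additional_r2 = unname(d$additional))
    }
    utils::write.csv(do.call(rbind, dec),
                     file.path(outDir, "partial_r2.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, add),
                     file.path(outDir, "additional_r2.csv"),
                     row.names = FALSE)
    pca <- pcaComposition(props, md)
    utils::write.csv(data.frame(sample_id = md$sample_id,
                                pca$scores[, 1:2, drop = FALSE]),
                     file.path(outDir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(pca$associations,
                     file.path(outDir, "pca_associations.csv"),
                     row.names = FALSE)
    emit(c("partial_r2.csv", "additional_r2.csv", "pca_scores.csv",
           "pca_associations.csv"))
    note("decompose: clocks=", length(clocks))
  }
  if ("confound" %in% stages) {
    caseLabel <- if (is.null(config$caseLabel)) "disease" else config$caseLabel
    cases <- md[md$disease == caseLabel, ]
    ctrls <- md[md$disease == "none", ]
    if (!nrow(cases)) {
      note("confound: skipped (no cases with label '", caseLabel, "')")
    } else {
      mt <- matchControls(cases, ctrls)
      utils::write.csv(mt$pairs, file.path(outDir, "matched_pairs.csv"),
                       row.names = FALSE)
      sel <- md$sample_id %in% c(mt$pairs$case_id, mt$pairs$control_id)
      rep_ <- confoundingReport(accel[accel$sample_id %in%
                                        md$sample_id[sel], ], md[sel, ])
      utils::write.csv(rep_, file.path(outDir, "confounding_effects.csv"),
                       row.names = FALSE)
      cd <- compositionDifference(proportions(props)[sel, , drop = FALSE],
                                  md$disease[sel] != "none")
      utils::write.csv(cd, file.path(outDir, "composition_difference.csv"),
                       row.names = FALSE)
      emit(c("matched_pairs.csv", "confounding_effects.csv",
             "composition_difference.csv"))
      note("confound: pairs=", nrow(mt$pairs),
           ", unmatched=", length(mt$unmatched))
    }
  }

  files <- file.path(outDir, artifacts)
  manifest <- list(
    package = as.character(utils::packageVersion("immunoEAA")),
    seed = seed,
    scenario = sc$name,
    stages = stages,
    artifacts = data.frame(file = artifacts,
                           md5 = unname(tools::md5sum(files))),
    log = unlist(log_)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Generate small in-memory fixtures
#'
#' A deterministic bundle for tests and examples: a 12-type reference
#' (3 markers per type), a 20-CpG drift panel, an n = 60 cohort with
#' diseased samples, three toy clocks spanning the families, and purified
#' mini-panels (6 samples per cell type).
#'
#' @param seed Integer seed.
#' @param dir Optional directory; when given, the fixtures are also
#'   written in their standard formats.
#' @return List with reference, driftModel, scenario, cohort, clocks,
#'   purified.
#' @export
makeFixtures <- function(seed = 1, dir = NULL) {
  sc <- defaultScenario(n = 60, diseasePrev = 0.25)
  ref <- generateReferenceLibrary(3, delta = 0.35,
                                  seed = deriveSeed(seed, 900))
  dm <- makeDriftModel(20, sc$driftSlope, seed = deriveSeed(seed, 901))
  cohort <- scenarioCohort(sc, reference = ref, driftModel = dm, seed = seed)
  clocks <- list(
    toyAge = generateClock(ref, dm, "age_scale", intrinsicFraction = 0.6,
                           seed = deriveSeed(seed, 1)),
    toyPace = generateClock(ref, dm, "pace_scale", intrinsicFraction = 0.25,
                            seed = deriveSeed(seed, 2)),
    toyMitotic = generateClock(ref, dm, "mitotic_scale",
                               intrinsicFraction = 0.15,
                               seed = deriveSeed(seed, 3))
  )
  purified <- generatePurifiedCohorts(ref, dm, nPerType = 6,
                                      seed = deriveSeed(seed, 4))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeBetaCsv(t(betaMatrix(cohort)), file.path(dir, "beta.csv"))
    utils::write.csv(sampleMetadata(cohort),
                     file.path(dir, "metadata.csv"), row.names = FALSE)
    writeReferenceCsv(ref, file.path(dir, "reference.csv"))
    for (nm in names(clocks))
      writeClockJson(clocks[[nm]], file.path(dir, paste0(nm, ".json")))
  }
  list(reference = ref, driftModel = dm, scenario = sc, cohort = cohort,
       clocks = clocks, purified = purified)
}
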