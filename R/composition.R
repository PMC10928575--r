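#' Construct a CompositionModel
#'
#' @param baselineLogits Named numeric vector (12 canonical cell types).
#' @param ageSlopes Per-year logit slopes (length 12).
#' @param ageKnots Plateau ages per cell (length 12, Inf = linear).
#' @param diseaseShifts Logit shifts for diseased samples (length 12).
#' @param dispersion Between-subject logit SD (>= 0, independent
#'   per-cell component).
#' @param axisLoadings Loadings of the shared between-subject factor
#'   (length 12; default zero).
#' @param axisSd SD of the shared factor (>= 0).
#' @param newbornOverrides Optional logit vector used at age exactly 0.
#' @return A \linkS4class{CompositionModel}.
#' @export
newCompositionModel <- function(baselineLogits,
                                ageSlopes = numeric(12),
                                ageKnots = rep(Inf, 12),
                                diseaseShifts = numeric(12),
                                dispersion = 0,
                                axisLoadings = numeric(12),
                                axisSd = 0,
                                newbornOverrides = numeric(0)) {
  if (is.null(names(baselineLogits)))
    names(baselineLogits) <- cellTypes12()
  new("CompositionModel",
      baselineLogits = baselineLogits[cellTypes12()],
      ageSlopes = unname(ageSlopes), ageKnots = unname(ageKnots),
      diseaseShifts = unname(diseaseShifts), dispersion = dispersion,
      axisLoadings = unname(axisLoadings), axisSd = axisSd,
      newbornOverrides = unname(newbornOverrides))
}

#' Default blood-aging composition model
#'
#' The default study conditions: baseline logits calibrated so that at age
#' 50 the expected composition matches typical adult whole blood
#' (neutrophil majority around 54\%, monocytes ~8\%, memory CD4/CD8 around
#' 7-8\%, minor populations 1-5\%); naive lymphocytes (Bnv, CD4nv, CD8nv)
#' decline at -0.02 logits/yr, memory lymphocytes (Bmem, CD4mem, CD8mem)
#' rise at +0.02 logits/yr, and neutrophils rise at +0.03 logits/yr up to
#' age 18 then plateau. Disease (rheumatoid-arthritis-like) shifts raise
#' Neu and Treg and lower the other lymphocyte subsets, Mono and NK.
#'
#' @param dispersion Between-subject logit SD (default 0.7, matching the
#'   large relative spread of the rare subsets in adult blood, where the
#'   SD of a rare cell's proportion is comparable to its mean).
#' @param memoryAxisSd SD of the shared antigen-experience factor that
#'   raises all memory-lymphocyte logits (+1 loading) and lowers all
#'   naive logits (-1) jointly, reflecting the co-movement of memory
#'   compartments with immune history (default 0.8).
#' @param diseaseShifts Optional replacement for the default shift vector.
#' @param newbornOverride Enable a newborn-specific logit override with
#'   elevated naive lymphocytes and a basophil-like (nucleated-RBC
#'   contamination analogue) excess at age 0. Default off.
#' @return A \linkS4class{CompositionModel}.
#' @examples
#' m <- bloodCompositionModel()
#' p <- sampleComposition(m, data.frame(sample_id = "s1", age = 50,
#'   sex = "Female", ancestry = "European", disease = "none"), seed = 1)
#' round(p, 3)
#' @export
bloodCompositionModel <- function(dispersion = 0.7, memoryAxisSd = 0.8,
                                  diseaseShifts = NULL,
                                  newbornOverride = FALSE) {
  cells <- cellTypes12()
  ## adult (age-50) target composition, renormalised
  p50 <- c(Bas = 0.013, Eos = 0.013, Neu = 0.543, Mono = 0.080,
           Bnv = 0.045, Bmem = 0.014, CD4nv = 0.053, CD4mem = 0.072,
           Treg = 0.013, CD8nv = 0.013, CD8mem = 0.079, NK = 0.046)
  p50 <- p50 / sum(p50)
  slopes <- stats::setNames(numeric(12), cells)
  slopes[naiveCells()] <- -0.02
  slopes[memoryCells()] <- +0.02
  slopes["Neu"] <- +0.03
  knots <- stats::setNames(rep(Inf, 12), cells)
  knots["Neu"] <- 18
  base <- log(p50) - slopes * pmin(50, knots)
  shifts <- stats::setNames(numeric(12), cells)
  shifts[c("Neu", "Treg")] <- c(0.45, 0.50)
  shifts[c("Bnv", "Bmem")] <- -0.40
  shifts[c("CD4nv", "CD4mem")] <- c(-0.30, -0.25)
  shifts[c("CD8nv", "CD8mem")] <- c(-0.40, -0.50)
  shifts[c("Mono", "NK")] <- -0.15
  if (!is.null(diseaseShifts)) shifts <- diseaseShifts[cells]
  nb <- numeric(0)
  if (newbornOverride) {
    nb <- base
    nb[naiveCells()] <- nb[naiveCells()] + 1.0
    nb["Bas"] <- nb["Bas"] + 1.5
  }
  axis <- stats::setNames(numeric(12), cells)
  axis[memoryCells()] <- 1
  axis[naiveCells()] <- -1
  newCompositionModel(base, ageSlopes = slopes, ageKnots = knots,
                      diseaseShifts = shifts, dispersion = dispersion,
                      axisLoadings = axis, axisSd = memoryAxisSd,
                      newbornOverrides = nb)
}

#' Sample true cell-type proportions
#'
#' Draws one composition per sample from the logistic-normal model:
#' softmax of baseline + age trend + disease shift + N(0, dispersion)
#' logits. With dispersion 0 the output is the deterministic softmax.
#'
#' @param model A \linkS4class{CompositionModel}.
#' @param metadata Data frame with at least \code{age} and \code{disease}
#'   (reference level "none") columns; row order is preserved.
#' @param seed Integer seed.
#' @return Samples x 12 matrix of proportions on the simplex.
#' @export
sampleComposition <- function(model, metadata, seed = 1) {
  stopifnot(is(model, "CompositionModel"))
  validObject(model)
  age <- metadata$age
  if (any(age < 0 | age > 99)) stop("ages must lie in [0, 99]")
  diseased <- as.numeric(metadata$disease != "none")
  k <- length(cellTypes12())
  n <- nrow(metadata)
  withSeed(seed, {
    logits <- matrix(rep(model@baselineLogits, each = n), n, k)
    if (length(model@newbornOverrides)) {
      nb <- which(age == 0)
      if (length(nb))
        logits[nb, ] <- matrix(rep(model@newbornOverrides, each = length(nb)),
                               length(nb), k)
    }
    ageEff <- outer(age, seq_len(k),
                    function(a, j) pmin(a, model@ageKnots[j]) * model@ageSlopes[j])
    logits <- logits + ageEff + outer(diseased, model@diseaseShifts)
    if (model@dispersion > 0)
      logits <- logits + matrix(stats::rnorm(n * k, 0, model@dispersion), n, k)
    if (model@axisSd > 0)
      logits <- logits +
        outer(stats::rnorm(n, 0, model@axisSd), model@axisLoadings)
    p <- softmaxRows(logits)
    dimnames(p) <- list(metadata$sample_id, cellTypes12())
    p
  })
}

#' Simulate sample metadata
#'
#' Draws ages (a point mass of newborns at exactly age 0, otherwise
#' uniform on [1, 99]), sex, a three-level ancestry, disease status
#' against a "none" reference, and a batch label assigned independently of
#' everything else (so batch is null by construction for the PCA QC).
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param newbornFrac Probability of age exactly 0 (default 0.1).
#' @param diseaseLabel Label given to diseased samples.
#' @param diseasePrev Disease prevalence (default 0).
#' @param ageRange Age range for the non-newborn samples.
#' @param nBatches Number of batch labels.
#' @param idPrefix Prefix for sample identifiers.
#' @return A data.frame usable as \code{colData} for a cohort.
#' @export
simulateSampleMetadata <- function(n, seed = 1, newbornFrac = 0.1,
                                   diseaseLabel = "disease",
                                   diseasePrev = 0,
                                   ageRange = c(1, 99), nBatches = 4,
                                   idPrefix = "s") {
  withSeed(seed, {
    age <- stats::runif(n, ageRange[1], ageRange[2])
    if (newbornFrac > 0)
      age[stats::runif(n) < newbornFrac] <- 0
    data.frame(
      sample_id = sprintf("%s%05d", idPrefix, seq_len(n)),
      age = age,
      sex = sample(c("Male", "Female"), n, replace = TRUE),
      ancestry = sample(c("European", "African", "EastAsian"), n,
                        replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      disease = ifelse(stats::runif(n) < diseasePrev, diseaseLabel, "none"),
      batch = paste0("batch", sample.int(nBatches, n, replace = TRUE)),
      stringsAsFactors = FALSE
    )
  })
}
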