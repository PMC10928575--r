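applyCalibration <- function(score, calibration) {
  switch(calibration$type,
    identity = score,
    log_linear = {
      a <- calibration$adult_age
      ifelse(score < 0, (1 + a) * exp(score) - 1, (1 + a) * score + a)
    },
    stop("unknown calibration type"))
}

#' Evaluate a clock on a cohort
#'
#' Computes methylation age \code{mage = calibration(intercept +
#' sum(w_c beta_c))} per sample. Samples for which more than
#' \code{maxMissingFrac} of the clock's CpGs are unavailable are masked
#' (NA); for unmasked samples, missing CpGs contribute zero to the linear
#' score by default, or the supplied reference means when
#' \code{imputeWith} is given.
#'
#' @param cohort A \linkS4class{MethylCohort} or samples x CpGs matrix.
#' @param clock A \linkS4class{ClockDefinition}.
#' @param maxMissingFrac Clock-level masking threshold (default 0.10).
#' @param imputeWith Optional named numeric vector of per-CpG fallback
#'   beta values used for missing clock CpGs.
#' @param ... Unused.
#' @return List with \code{mage} (numeric, NA where masked) and
#'   \code{masked} (logical).
#' @rdname computeMAge
#' @export
setMethod("computeMAge", signature("matrix", "ClockDefinition"),
  function(cohort, clock, maxMissingFrac = 0.10, imputeWith = NULL, ...) {
    w <- clock@weights
    resolvable <- intersect(names(w), colnames(cohort))
    if (!length(resolvable))
      stop("configuration error: no clock CpGs resolvable in the cohort")
    masked <- applyLibraryMasking(cohort, names(w), maxMissingFrac)
    B <- matrix(0, nrow(cohort), length(w),
                dimnames = list(rownames(cohort), names(w)))
    B[, resolvable] <- cohort[, resolvable]
    if (!is.null(imputeWith)) {
      for (cg in names(w)) {
        bad <- if (cg %in% resolvable) is.na(cohort[, cg]) else
          rep(TRUE, nrow(cohort))
        if (any(bad) && cg %in% names(imputeWith))
          B[bad, cg] <- imputeWith[cg]
      }
    }
    B[is.na(B)] <- 0
    mage <- applyCalibration(clock@intercept + drop(B %*% w),
                             clock@calibration)
    mage[masked] <- NA_real_
    list(mage = mage, masked = masked)
  })

#' @rdname computeMAge
#' @export
setMethod("computeMAge", signature("MethylCohort", "ClockDefinition"),
  function(cohort, clock, maxMissingFrac = 0.10, imputeWith = NULL, ...) {
    computeMAge(t(betaMatrix(cohort)), clock,
                maxMissingFrac = maxMissingFrac, imputeWith = imputeWith)
  })

#' Residual epigenetic age acceleration
#'
#' EAA as the ordinary-least-squares residual of methylation age on
#' (intercept, chronological age), computed within the supplied
#' population. By construction the residuals have mean zero and zero
#' sample covariance with age. When age is constant (e.g. a newborn-only
#' population) the residual is undefined and the function falls back to
#' centred methylation age, with a warning.
#'
#' @param mage Methylation ages (NA = masked, left NA in the output).
#' @param age Chronological ages.
#' @return Numeric vector of residuals (NA where mage is NA).
#' @export
eaaResidual <- function(mage, age) {
  ok <- !is.na(mage) & !is.na(age)
  if (sum(ok) < 3L)
    stop("need at least 3 unmasked samples to residualise")
  out <- rep(NA_real_, length(mage))
  if (stats::var(age[ok]) == 0) {
    warning("degenerate design: constant age; using centred mage")
    out[ok] <- mage[ok] - mean(mage[ok])
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, age[ok]), mage[ok])
  out[ok] <- fit$residuals
  out
}

#' Difference epigenetic age acceleration
#'
#' \code{mage - age}; defined only for age-scale clocks (pace and mitotic
#' clocks are not reported in years).
#'
#' @param mage Methylation ages.
#' @param age Chronological ages.
#' @param family Clock family; non-"age_scale" is an error.
#' @return Numeric vector.
#' @export
eaaDifference <- function(mage, age, family = "age_scale") {
  if (!identical(family, "age_scale"))
    stop("difference EAA is defined only for age_scale clocks")
  mage - age
}

#' Intrinsic epigenetic age acceleration
#'
#' Residuals of methylation age on (intercept, age, cell-type block) in a
#' single regression. The six-cell block aggregates the 12-cell estimates
#' (Bcell, CD4T, Gran sums plus CD8nv, CD8mem, Mono); the eleven-cell
#' block is the full panel minus NK. A two-stage alternative
#' (residualising EAA on the cells) is available via \code{twoStage}.
#'
#' @param mage Methylation ages (NA = masked).
#' @param age Chronological ages.
#' @param proportions A \linkS4class{CellProportions} or samples x 12
#'   matrix aligned with \code{mage}.
#' @param cellSet "eleven" (default) or "six".
#' @param twoStage Residualise EAA (not mage) on the cell block.
#' @return Numeric vector of IEAA values (NA where input is NA).
#' @export
computeIEAA <- function(mage, age, proportions,
                        cellSet = c("eleven", "six"), twoStage = FALSE) {
  cellSet <- match.arg(cellSet)
  p <- if (is(proportions, "CellProportions")) proportions(proportions)
       else proportions
  block <- if (cellSet == "six") aggregateSixCells(p)
           else p[, cellTypes11(), drop = FALSE]
  ok <- !is.na(mage) & !is.na(age) & stats::complete.cases(block)
  if (sum(ok) < ncol(block) + 3L)
    stop("too few unmasked samples for the cell-adjusted residual")
  y <- if (twoStage) eaaResidual(mage, age)[ok] else mage[ok]
  X <- cbind(`(Intercept)` = 1, age = age[ok], block[ok, , drop = FALSE])
  if (twoStage) X <- X[, colnames(X) != "age", drop = FALSE]
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    warning("collinear cell block: ",
            paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "),
            " dropped")
  out <- rep(NA_real_, length(mage))
  out[ok] <- fit$residuals
  out
}

#' Build the per-sample age-acceleration table
#'
#' Evaluates each clock on the cohort, applies clock-level masking, and
#' derives the five acceleration variants: residual EAA, difference EAA
#' (age-scale clocks only), and IEAA adjusted for six or eleven cell
#' types. Residualisations are computed within the supplied population.
#'
#' @param cohort A \linkS4class{MethylCohort}.
#' @param clocks A \linkS4class{ClockDefinition} or list of them.
#' @param proportions A \linkS4class{CellProportions} (or samples x 12
#'   matrix) aligned with the cohort's samples.
#' @param ... Passed to \code{\link{computeMAge}}.
#' @return A long data.frame (sample_id, clock, family, masked, mage,
#'   eaa_resid, eaa_diff, ieaa6, ieaa11).
#' @export
ageAccelTable <- function(cohort, clocks, proportions, ...) {
  if (is(clocks, "ClockDefinition")) clocks <- list(clocks)
  md <- sampleMetadata(cohort)
  p <- if (is(proportions, "CellProportions")) proportions(proportions)
       else proportions
  out <- lapply(clocks, function(ck) {
    ev <- computeMAge(cohort, ck, ...)
    data.frame(
      sample_id = md$sample_id,
      clock = ck@name,
      family = ck@family,
      masked = ev$masked,
      mage = ev$mage,
      eaa_resid = eaaResidual(ev$mage, md$age),
      eaa_diff = if (ck@family == "age_scale")
        eaaDifference(ev$mage, md$age) else NA_real_,
      ieaa6 = computeIEAA(ev$mage, md$age, p, "six"),
      ieaa11 = computeIEAA(ev$mage, md$age, p, "eleven"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Clock performance in purified cell populations
#'
#' Regresses methylation age on chronological age within each purified
#' cell type (reporting Pearson r, R-squared, age-prediction RMSE and the
#' slope p-value), and derives EAA from a single pooled mage-on-age
#' regression across all purified samples so that EAA levels are
#' comparable between cell types.
#'
#' @param purifiedCohorts Named list of per-cell-type
#'   \linkS4class{MethylCohort} (see
#'   \code{\link{generatePurifiedCohorts}}).
#' @param clocks A \linkS4class{ClockDefinition} or list of them.
#' @return List with \code{stats} (cell x clock regression metrics) and
#'   \code{eaa} (per-sample pooled and within-cell EAA).
#' @export
evaluatePurified <- function(purifiedCohorts, clocks) {
  if (is(clocks, "ClockDefinition")) clocks <- list(clocks)
  stats_ <- list()
  eaa_ <- list()
  for (ck in clocks) {
    per <- lapply(names(purifiedCohorts), function(cell) {
      ch <- purifiedCohorts[[cell]]
      ev <- computeMAge(ch, ck)
      data.frame(cell = cell, sample_id = sampleMetadata(ch)$sample_id,
                 age = sampleMetadata(ch)$age, mage = ev$mage,
                 stringsAsFactors = FALSE)
    })
    pooled <- do.call(rbind, per)
    pooled$eaa_pooled <- eaaResidual(pooled$mage, pooled$age)
    pooled$eaa_within <- NA_real_
    for (cell in names(purifiedCohorts)) {
      d <- pooled[pooled$cell == cell & !is.na(pooled$mage), ]
      if (nrow(d) < 3L) {
        warning("skipping ", cell, " for ", ck@name, ": fewer than 3 samples")
        next
      }
      fit <- summary(stats::lm(mage ~ age, data = d))
      r <- stats::cor(d$mage, d$age)
      stats_[[length(stats_) + 1L]] <- data.frame(
        cell = cell, clock = ck@name, n = nrow(d), r = r, r2 = r^2,
        rmse = sqrt(mean((d$mage - d$age)^2)),
        p = fit$coefficients["age", "Pr(>|t|)"],
        stringsAsFactors = FALSE)
      pooled$eaa_within[pooled$cell == cell] <-
        eaaResidual(pooled$mage[pooled$cell == cell],
                    pooled$age[pooled$cell == cell])
    }
    pooled$clock <- ck@name
    eaa_[[length(eaa_) + 1L]] <- pooled
  }
  list(stats = do.call(rbind, stats_), eaa = do.call(rbind, eaa_))
}
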