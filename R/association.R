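#' Age-group assignment
#'
#' Three analysis strata: newborns (age exactly 0), pediatric (0 <= age
#' < 18, newborns included), and adults (18 <= age <= 99). Every sample
#' belongs to exactly one of pediatric/adult; newborns additionally form
#' their own stratum.
#'
#' @param age Numeric ages in years.
#' @return Data frame of logicals with columns newborn, pediatric, adult.
#' @export
assignAgeGroups <- function(age) {
  if (any(age < 0 | age > 99)) stop("ages must lie in [0, 99]")
  data.frame(newborn = age == 0,
             pediatric = age < 18,
             adult = age >= 18)
}

#' Z-score within groups
#'
#' Standardises values to mean 0, sample SD 1 (n-1 denominator) within
#' each group; NAs are ignored in the group moments and propagated.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (a single group when
#'   NULL).
#' @return Numeric vector of z-scores.
#' @export
zscoreByGroup <- function(values, groups = NULL) {
  if (is.null(groups)) groups <- rep(1L, length(values))
  out <- rep(NA_real_, length(values))
  for (g in unique(groups)) {
    sel <- groups == g & !is.na(values)
    if (sum(sel) < 2L)
      stop("degenerate group '", g, "': fewer than 2 values")
    s <- stats::sd(values[sel])
    if (s == 0)
      stop("degenerate group '", g, "': zero variance")
    out[sel] <- (values[sel] - mean(values[sel])) / s
  }
  out
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjusted q-values (via \code{stats::p.adjust}) and rejection
#' flags at the requested FDR level.
#'
#' @param p P-values in [0, 1].
#' @param qLevel FDR level (default 0.05).
#' @return List with \code{q} and logical \code{reject}.
#' @export
bhFdr <- function(p, qLevel = 0.05) {
  if (!length(p)) return(list(q = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= qLevel)
}

## Covariate design with deterministic dropping of constant and collinear
## columns. Drop priority when rank-deficient: age^2 first, then age, then
## ancestry indicator columns ordered by increasing level frequency.
buildCovariateDesign <- function(metadata, multiLevelDisease = FALSE) {
  n <- nrow(metadata)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  dropped <- character(0)
  addCol <- function(X, x, nm) {
    if (length(unique(x[!is.na(x)])) < 2L) {
      dropped <<- c(dropped, nm)
      return(X)
    }
    cbind(X, stats::setNames(data.frame(x), nm))
  }
  X <- as.matrix(addCol(as.data.frame(X),
                        as.numeric(metadata$sex == "Male"), "sexMale"))
  anc <- factor(metadata$ancestry)
  if (nlevels(anc) > 1L) {
    lev <- names(sort(table(anc), decreasing = TRUE))
    for (l in lev[-1L])
      X <- as.matrix(addCol(as.data.frame(X), as.numeric(anc == l),
                            paste0("ancestry", l)))
  } else dropped <- c(dropped, "ancestry")
  if (multiLevelDisease) {
    dis <- factor(metadata$disease)
    if ("none" %in% levels(dis)) dis <- stats::relevel(dis, "none")
    for (l in levels(dis)[-1L])
      X <- as.matrix(addCol(as.data.frame(X), as.numeric(dis == l),
                            paste0("disease", l)))
  } else {
    X <- as.matrix(addCol(as.data.frame(X),
                          as.numeric(metadata$disease != "none"), "disease"))
  }
  X <- as.matrix(addCol(as.data.frame(X), metadata$age, "age"))
  X <- as.matrix(addCol(as.data.frame(X), metadata$age^2, "age2"))
  ## deterministic collinearity resolution
  priority <- c("age2", "age",
                rev(grep("^ancestry", colnames(X), value = TRUE)))
  for (nm in priority) {
    if (qr(X)$rank == ncol(X)) break
    if (nm %in% colnames(X)) {
      X <- X[, colnames(X) != nm, drop = FALSE]
      dropped <- c(dropped, nm)
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("covariate design remains rank-deficient after dropping")
  attr(X, "dropped") <- dropped
  X
}

## OLS with standard t-tests from the normal equations.
olsFit <- function(X, y) {
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("not enough observations for the model")
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    stop("unestimable model: ",
         paste(colnames(X)[is.na(fit$coefficients)], collapse = ", "))
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  tval <- fit$coefficients / se
  list(coef = fit$coefficients, se = se,
       p = 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE),
       n = n, residuals = fit$residuals, rss = rss, df = n - p)
}

#' Per-cell association model
#'
#' OLS of a z-scored acceleration value on one z-scored cell proportion,
#' adjusting for sex, ancestry, disease status, age and age-squared (the
#' quadratic term absorbs the nonlinear dependence of clock accuracy on
#' age). Constant or collinear covariates (e.g. age in a newborn-only
#' group) are dropped deterministically. The reported coefficient is the
#' standardized per-SD association of the cell with the acceleration
#' measure.
#'
#' @param eaaZ Z-scored acceleration values.
#' @param cellZ Z-scored cell proportion.
#' @param metadata Data frame with sex, ancestry, disease, age.
#' @param multiLevelDisease Encode disease as multi-level factor instead
#'   of a single any-disease indicator.
#' @return One-row data.frame: beta, se, p, n, dropped.
#' @export
fitCellModel <- function(eaaZ, cellZ, metadata, multiLevelDisease = FALSE) {
  X0 <- buildCovariateDesign(metadata, multiLevelDisease)
  X <- cbind(X0[, 1, drop = FALSE], cell_z = cellZ,
             X0[, -1, drop = FALSE])
  attr(X, "dropped") <- attr(X0, "dropped")
  f <- olsFit(X, eaaZ)
  data.frame(beta = unname(f$coef["cell_z"]), se = unname(f$se["cell_z"]),
             p = unname(f$p["cell_z"]), n = f$n,
             dropped = paste(attr(X, "dropped"), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Mutually adjusted association model
#'
#' A single OLS of the z-scored acceleration on all eleven cell-type
#' z-scores simultaneously (NK excluded to avoid the compositional
#' collinearity) plus the standard covariates, giving each cell's
#' association conditional on the rest of the immune profile.
#'
#' @param eaaZ Z-scored acceleration values.
#' @param cellZ Samples x cells matrix of z-scored proportions; the
#'   eleven-cell subset is selected by name.
#' @param metadata Data frame with sex, ancestry, disease, age.
#' @param conditionThreshold Design condition number above which a
#'   collinearity warning with variance-inflation factors is emitted.
#' @return Data frame, one row per cell: cell, beta, se, p, n.
#' @export
fitMutuallyAdjustedModel <- function(eaaZ, cellZ, metadata,
                                     conditionThreshold = 1e8) {
  cells <- intersect(cellTypes11(), colnames(cellZ))
  if (length(cells) != 11L)
    stop("need the 11 canonical cell columns (NK excluded)")
  Z <- cellZ[, cellTypes11(), drop = FALSE]
  X <- buildCovariateDesign(metadata)
  X <- cbind(X[, 1, drop = FALSE], Z, X[, -1, drop = FALSE])
  kap <- kappa(X, exact = FALSE)
  if (is.finite(kap) && kap > conditionThreshold) {
    cc <- stats::cor(Z, use = "pairwise")
    vif <- diag(solve(cc))
    warning("ill-conditioned design (kappa = ", signif(kap, 3), "); VIF: ",
            paste(sprintf("%s=%.1f", colnames(Z), vif), collapse = ", "))
  }
  f <- olsFit(X, eaaZ)
  data.frame(cell = cellTypes11(),
             beta = unname(f$coef[cellTypes11()]),
             se = unname(f$se[cellTypes11()]),
             p = unname(f$p[cellTypes11()]),
             n = f$n, stringsAsFactors = FALSE)
}

#' Run the full association grid
#'
#' Iterates clocks x cell types x age groups x acceleration variants:
#' z-scores the acceleration and the cell proportions within each age
#' group, fits the per-cell adjusted model for each of the 12 cells, fits
#' the mutually adjusted eleven-cell model when requested, and applies
#' Benjamini-Hochberg FDR within the configured family (default: per
#' clock x age group x variant across cells). Groups too small to fit are
#' emitted with NA estimates and their n, so runs complete gracefully.
#'
#' @param accel Age-acceleration table from \code{\link{ageAccelTable}}.
#' @param proportions \linkS4class{CellProportions} or samples x 12
#'   matrix, rows aligned with the cohort metadata.
#' @param metadata Sample metadata (sample_id, age, sex, ancestry,
#'   disease).
#' @param variants Acceleration variants to test.
#' @param mutual Also fit the mutually adjusted model (on eaa_resid).
#' @param fdrFamily "per_clock_group" (default) or "global".
#' @param qLevel FDR level for the stars/rejection flags.
#' @return Long data.frame: clock, cell, age_group, variant, model, beta,
#'   se, p, q, n, stars.
#' @export
runAssociationGrid <- function(accel, proportions, metadata,
                               variants = c("eaa_resid", "ieaa6", "ieaa11"),
                               mutual = TRUE,
                               fdrFamily = c("per_clock_group", "global"),
                               qLevel = 0.05) {
  fdrFamily <- match.arg(fdrFamily)
  p12 <- if (is(proportions, "CellProportions")) proportions(proportions)
         else proportions
  stopifnot(nrow(p12) == nrow(metadata))
  groups <- assignAgeGroups(metadata$age)
  rows <- list()
  for (clk in unique(accel$clock)) {
    a <- accel[accel$clock == clk, ]
    a <- a[match(metadata$sample_id, a$sample_id), ]
    if (any(is.na(a$sample_id) & !is.na(metadata$sample_id)))
      stop("join error: accel table missing samples: ",
           paste(utils::head(setdiff(metadata$sample_id, a$sample_id), 5),
                 collapse = ", "))
    for (grp in colnames(groups)) {
      sel <- groups[[grp]]
      for (v in variants) {
        y <- a[[v]][sel]
        ok <- !is.na(y)
        fitOne <- function(expr) {
          tryCatch(expr, error = function(e)
            data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                       n = sum(ok), dropped = NA_character_,
                       stringsAsFactors = FALSE))
        }
        canFit <- sum(ok) >= 15L && !all(is.na(y)) && sdSafe(y[ok]) > 0
        yz <- if (canFit) zscoreByGroup(y) else y
        md <- metadata[sel, ]
        res <- lapply(cellTypes12(), function(cell) {
          f <- if (!canFit)
            data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                       n = sum(ok), dropped = NA_character_,
                       stringsAsFactors = FALSE)
          else fitOne(fitCellModel(yz, zscoreByGroup(p12[sel, cell]), md))
          cbind(data.frame(clock = clk, cell = cell, age_group = grp,
                           variant = v, model = "per_cell",
                           stringsAsFactors = FALSE),
                f[, c("beta", "se", "p", "n")])
        })
        rows <- c(rows, res)
        if (mutual && v == "eaa_resid" && canFit) {
          mres <- tryCatch({
            Z <- apply(p12[sel, cellTypes11(), drop = FALSE], 2,
                       zscoreByGroup)
            m <- fitMutuallyAdjustedModel(yz, Z, md)
            cbind(data.frame(clock = clk, cell = m$cell, age_group = grp,
                             variant = v, model = "mutually_adjusted",
                             stringsAsFactors = FALSE),
                  m[, c("beta", "se", "p", "n")])
          }, error = function(e) NULL)
          if (!is.null(mres)) rows <- c(rows, list(mres))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  ## FDR within the configured family
  out$q <- NA_real_
  fam <- if (fdrFamily == "global") rep("all", nrow(out)) else
    paste(out$clock, out$age_group, out$variant, out$model)
  for (f in unique(fam)) {
    i <- which(fam == f & !is.na(out$p))
    if (length(i)) out$q[i] <- bhFdr(out$p[i], qLevel)$q
  }
  out$stars <- ifelse(is.na(out$q), "",
                ifelse(out$q < 0.001, "***",
                 ifelse(out$q < 0.01, "**",
                  ifelse(out$q < 0.05, "*", ""))))
  rownames(out) <- NULL
  out
}
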