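#' Full-model design for variance decomposition
#'
#' Builds the design used by the partial-R-squared analysis: eleven cell
#' proportions (NK excluded for collinearity), sex, ancestry, disease,
#' age and age-squared. Returns the design matrix plus the column index
#' of each covariate block.
#'
#' @param proportions Samples x 12 proportions matrix (or
#'   \linkS4class{CellProportions}).
#' @param metadata Sample metadata data.frame.
#' @return List with \code{X} (matrix, intercept first) and
#'   \code{blocks} (named list of column names per block).
#' @export
buildEaaDesign <- function(proportions, metadata) {
  p <- if (is(proportions, "CellProportions")) proportions(proportions)
       else proportions
  cells <- p[, cellTypes11(), drop = FALSE]
  X <- buildCovariateDesign(metadata)
  full <- cbind(X[, 1, drop = FALSE], cells, X[, -1, drop = FALSE])
  blocks <- list(
    cells = cellTypes11(),
    sex = intersect("sexMale", colnames(full)),
    ancestry = grep("^ancestry", colnames(full), value = TRUE),
    disease = grep("^disease", colnames(full), value = TRUE),
    age = intersect(c("age", "age2"), colnames(full))
  )
  list(X = full, blocks = blocks)
}

#' Partial R-squared of a covariate block
#'
#' \code{1 - SSE_full / SSE_reduced}, where the reduced model drops
#' exactly the block's columns from the full design: the share of outcome
#' variance attributable to the block given the rest of the model.
#'
#' @param y Outcome (e.g. residual EAA for one clock).
#' @param fullDesign Full design matrix including an intercept.
#' @param blockColumns Column names of the block to test.
#' @return Scalar partial R-squared in [0, 1].
#' @export
partialR2 <- function(y, fullDesign, blockColumns) {
  if (!all(blockColumns %in% colnames(fullDesign)))
    stop("block columns not in the design: ",
         paste(setdiff(blockColumns, colnames(fullDesign)), collapse = ", "))
  keep <- setdiff(colnames(fullDesign), blockColumns)
  ok <- stats::complete.cases(fullDesign) & !is.na(y)
  Xf <- fullDesign[ok, , drop = FALSE]
  Xr <- fullDesign[ok, keep, drop = FALSE]
  if (qr(Xr)$rank < ncol(Xr))
    stop("estimability error: reduced model is rank-deficient")
  sseF <- sum(stats::lm.fit(Xf, y[ok])$residuals^2)
  sseR <- sum(stats::lm.fit(Xr, y[ok])$residuals^2)
  if (sseR <= 0) return(0)
  max(0, min(1, 1 - sseF / sseR))
}

#' Additional R-squared of one cell type
#'
#' Increase in model R-squared when a single cell proportion is added to
#' the baseline model (intercept, sex, ancestry, disease, age, age^2).
#' Computed one cell at a time for each of the 12 cell types (NK
#' included: the one-at-a-time models have no compositional collinearity).
#'
#' @param y Outcome.
#' @param baselineDesign Baseline design matrix including an intercept.
#' @param cellColumn Numeric vector: the cell proportion to add.
#' @return Scalar additional R-squared (>= 0).
#' @export
additionalR2 <- function(y, baselineDesign, cellColumn) {
  ok <- stats::complete.cases(baselineDesign) & !is.na(y) & !is.na(cellColumn)
  X0 <- baselineDesign[ok, , drop = FALSE]
  X1 <- cbind(X0, cell = cellColumn[ok])
  if (qr(X1)$rank < ncol(X1)) {
    warning("cell column collinear with the baseline; additional R2 = 0")
    return(0)
  }
  yc <- y[ok]
  tss <- sum((yc - mean(yc))^2)
  if (tss <= 0) return(0)
  r20 <- 1 - sum(stats::lm.fit(X0, yc)$residuals^2) / tss
  r21 <- 1 - sum(stats::lm.fit(X1, yc)$residuals^2) / tss
  max(0, r21 - r20)
}

#' Variance decomposition of EAA per clock
#'
#' Convenience wrapper producing the block-wise partial R-squared (cells,
#' age, disease, sex, ancestry) and the per-cell additional R-squared for
#' one acceleration outcome.
#'
#' @param y Acceleration values (raw residual EAA; R-squared is
#'   scale-free).
#' @param proportions Samples x 12 matrix or \linkS4class{CellProportions}.
#' @param metadata Sample metadata.
#' @return List with \code{partial} (named numeric per block) and
#'   \code{additional} (named numeric per cell type).
#' @export
decomposeEaaVariance <- function(y, proportions, metadata) {
  p <- if (is(proportions, "CellProportions")) proportions(proportions)
       else proportions
  d <- buildEaaDesign(p, metadata)
  partial <- vapply(d$blocks, function(cols) {
    if (!length(cols)) return(NA_real_)
    partialR2(y, d$X, cols)
  }, numeric(1))
  base <- d$X[, setdiff(colnames(d$X), cellTypes11()), drop = FALSE]
  additional <- vapply(cellTypes12(), function(cell)
    additionalR2(y, base, p[, cell]), numeric(1))
  list(partial = partial, additional = additional)
}

#' PCA of immune cell composition
#'
#' Singular-value decomposition of the centred (optionally scaled)
#' proportions matrix, with association of the top components against
#' metadata covariates: ANOVA F-tests for categorical variables (batch,
#' disease, sex, ancestry) and Pearson correlation tests for age. Used as
#' a batch-effect QC: batch labels assigned independently of composition
#' should show no PC association.
#'
#' @param proportions Samples x 12 matrix or \linkS4class{CellProportions}.
#' @param metadata Sample metadata with optional batch column.
#' @param scale. Scale columns to unit variance before the SVD.
#' @param nPCs Number of components to report (>= 2).
#' @return List with \code{scores}, \code{loadings}, \code{varExplained}
#'   and \code{associations} (PC x covariate table with statistic and p).
#' @export
pcaComposition <- function(proportions, metadata, scale. = FALSE,
                           nPCs = 2) {
  p <- if (is(proportions, "CellProportions")) proportions(proportions)
       else proportions
  ok <- stats::complete.cases(p)
  p <- p[ok, , drop = FALSE]
  metadata <- metadata[ok, , drop = FALSE]
  if (nrow(p) < 3L) stop("need at least 3 samples for PCA")
  if (all(apply(p, 2, sdSafe) == 0))
    stop("degenerate composition matrix: no variance")
  pc <- stats::prcomp(p, center = TRUE, scale. = scale.)
  nPCs <- max(2L, min(nPCs, ncol(pc$x)))
  varExpl <- pc$sdev^2 / sum(pc$sdev^2)
  assoc <- list()
  vars <- intersect(c("batch", "disease", "sex", "ancestry", "age"),
                    colnames(metadata))
  for (i in seq_len(nPCs)) {
    for (v in vars) {
      x <- metadata[[v]]
      if (v == "age") {
        ct <- stats::cor.test(pc$x[, i], x)
        assoc[[length(assoc) + 1L]] <- data.frame(
          pc = i, covariate = v, test = "pearson",
          statistic = unname(ct$estimate), p = ct$p.value)
      } else if (length(unique(x)) > 1L) {
        af <- summary(stats::aov(pc$x[, i] ~ factor(x)))[[1]]
        assoc[[length(assoc) + 1L]] <- data.frame(
          pc = i, covariate = v, test = "anovaF",
          statistic = af[["F value"]][1], p = af[["Pr(>F)"]][1])
      }
    }
  }
  list(scores = pc$x, loadings = pc$rotation, varExplained = varExpl,
       associations = do.call(rbind, assoc))
}
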