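#' Canonical immune cell types
#'
#' The twelve leukocyte subtypes resolved by extended blood methylation
#' deconvolution, in canonical order: basophils (Bas), eosinophils (Eos),
#' neutrophils (Neu), monocytes (Mono), naive and memory B cells (Bnv,
#' Bmem), naive and memory CD4 T cells (CD4nv, CD4mem), regulatory T cells
#' (Treg), naive and memory CD8 T cells (CD8nv, CD8mem), and natural
#' killer cells (NK).
#'
#' @return Character vector of length 12.
#' @examples
#' cellTypes12()
#' @export
cellTypes12 <- function() {
  c("Bas", "Eos", "Neu", "Mono", "Bnv", "Bmem",
    "CD4nv", "CD4mem", "Treg", "CD8nv", "CD8mem", "NK")
}

#' Eleven-cell adjustment set (NK excluded)
#'
#' The cell set used for the granular intrinsic-EAA adjustment and for the
#' joint (mutually adjusted) models. NK is excluded so that the eleven
#' proportions plus the implicit remainder do not form an exactly
#' collinear block with the intercept.
#'
#' @return Character vector of length 11.
#' @export
cellTypes11 <- function() setdiff(cellTypes12(), "NK")

#' Traditional six-cell adjustment set
#'
#' Aggregates of the 12-cell estimates used for the classical intrinsic
#' EAA: Bcell = Bnv + Bmem, CD4T = CD4nv + CD4mem + Treg,
#' Gran = Neu + Eos + Bas, plus CD8nv, CD8mem and Mono.
#'
#' @return Character vector of length 6.
#' @export
cellTypes6 <- function() c("CD8nv", "CD8mem", "Bcell", "Mono", "CD4T", "Gran")

naiveCells <- function() c("Bnv", "CD4nv", "CD8nv")
memoryCells <- function() c("Bmem", "CD4mem", "CD8mem")

#' Aggregate 12-cell proportions into the six traditional cell types
#'
#' @param p Numeric matrix (samples x 12) with the canonical cell-type
#'   columns, or a vector of length 12.
#' @return Matrix (samples x 6) with columns \code{cellTypes6()}.
#' @export
aggregateSixCells <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  stopifnot(all(cellTypes12() %in% colnames(p)))
  cbind(
    CD8nv = p[, "CD8nv"],
    CD8mem = p[, "CD8mem"],
    Bcell = p[, "Bnv"] + p[, "Bmem"],
    Mono = p[, "Mono"],
    CD4T = p[, "CD4nv"] + p[, "CD4mem"] + p[, "Treg"],
    Gran = p[, "Neu"] + p[, "Eos"] + p[, "Bas"]
  )
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

## Rows of a matrix of logits -> rows on the simplex.
softmaxRows <- function(m) {
  t(apply(m, 1L, softmax))
}

#' Evaluate expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so seeded generators never perturb user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a deterministic sub-seed
#'
#' Maps a master seed and a stage index to a distinct integer seed (kept
#' well below the 32-bit limit), so every stage of a pipeline or
#' experiment draws from its own reproducible stream.
#'
#' @param seed Master integer seed.
#' @param k Stage index.
#' @return A single integer seed.
#' @export
deriveSeed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7L + 13L
}

## Beta draw parameterised by mean and precision; precision = Inf returns
## the mean exactly. var = mu * (1 - mu) / (1 + precision).
rbetaMeanPrec <- function(n, mu, precision) {
  if (is.infinite(precision)) return(rep_len(mu, n))
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  stats::rbeta(n, shape1 = mu * precision, shape2 = (1 - mu) * precision)
}

## Sample standard deviation that tolerates length-1 input.
sdSafe <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
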