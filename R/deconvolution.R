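## Active-set solvers in Gram form: minimise ||A w - b||^2, i.e.
## (1/2) w' G w - c' w with G = A'A, c = A'b, subject to w >= 0 and
## optionally sum(w) = 1. Dimensions are tiny (12 cells), so dense
## normal-equation solves are exact and fast. Ties in the entering
## variable are broken by lowest index (which.max returns the first
## maximum), making the solution path deterministic.

nnlsGram <- function(G, c0, tol = 1e-9, maxIter = 500L) {
  k <- length(c0)
  w <- numeric(k)
  P <- logical(k)
  for (iter in seq_len(maxIter)) {
    mu <- c0 - drop(G %*% w)
    cand <- which(!P & mu > tol)
    if (!length(cand)) return(w)
    P[cand[which.max(mu[cand])]] <- TRUE
    repeat {
      idx <- which(P)
      z <- solve(G[idx, idx, drop = FALSE], c0[idx])
      if (all(z > 0)) {
        w[] <- 0
        w[idx] <- z
        break
      }
      neg <- which(z <= 0)
      alpha <- min(w[idx][neg] / (w[idx][neg] - z[neg]))
      w[idx] <- w[idx] + alpha * (z - w[idx])
      zeroed <- idx[w[idx] <= tol]
      P[zeroed] <- FALSE
      w[zeroed] <- 0
    }
  }
  stop("active-set NNLS failed to converge")
}

simplexGram <- function(G, c0, tol = 1e-9, maxIter = 500L) {
  k <- length(c0)
  ## start from the best single-cell vertex (lowest index on ties)
  w <- numeric(k)
  j0 <- which.min(diag(G) - 2 * c0)
  w[j0] <- 1
  P <- logical(k)
  P[j0] <- TRUE
  lambda <- 0
  for (iter in seq_len(maxIter)) {
    repeat {
      idx <- which(P)
      m <- length(idx)
      KKT <- rbind(cbind(G[idx, idx, drop = FALSE], rep(1, m)),
                   c(rep(1, m), 0))
      sol <- solve(KKT, c(c0[idx], 1))
      z <- sol[seq_len(m)]
      lambda <- sol[m + 1L]
      if (all(z > -1e-14)) {
        w[] <- 0
        w[idx] <- pmax(z, 0)
        break
      }
      neg <- which(z <= 0)
      alpha <- min(w[idx][neg] / (w[idx][neg] - z[neg]))
      w[idx] <- w[idx] + alpha * (z - w[idx])
      zeroed <- idx[w[idx] <= tol]
      if (length(zeroed) == length(idx))          # keep the largest alive
        zeroed <- setdiff(zeroed, idx[which.max(w[idx])])
      P[zeroed] <- FALSE
      w[zeroed] <- 0
    }
    mu <- c0 - drop(G %*% w) - lambda
    cand <- which(!P & mu > tol)
    if (!length(cand)) return(w)
    P[cand[which.max(mu[cand])]] <- TRUE
  }
  stop("active-set simplex solver failed to converge")
}

## One sample: Gram-form solve under the chosen sum constraint.
solveProportions <- function(G, c0, constraint) {
  if (constraint == "eq_one") return(simplexGram(G, c0))
  w <- nnlsGram(G, c0)
  if (sum(w) > 1 + 1e-9) w <- simplexGram(G, c0)
  w
}

#' Library-level QC masking
#'
#' A sample is masked when more than \code{maxMissingFrac} of the library
#' CpGs are unavailable for it (absent from the matrix or NA), matching
#' the ">10\% of library CpGs failed" masking rule used for both
#' deconvolution and clock evaluation. The boundary is strict: exactly
#' 10\% missing is kept.
#'
#' @param beta Samples x CpGs matrix.
#' @param cpgSet CpG identifiers constituting the library.
#' @param maxMissingFrac Masking threshold (default 0.10).
#' @return Logical vector, TRUE for masked samples.
#' @examples
#' b <- matrix(0.5, 2, 100, dimnames = list(NULL, paste0("cg", 1:100)))
#' b[1, 1:10] <- NA   # exactly 10%: kept
#' b[2, 1:11] <- NA   # >10%: masked
#' applyLibraryMasking(b, paste0("cg", 1:100))
#' @export
applyLibraryMasking <- function(beta, cpgSet, maxMissingFrac = 0.10) {
  if (!length(cpgSet)) stop("cpgSet must be non-empty")
  present <- intersect(cpgSet, colnames(beta))
  nAbsent <- length(cpgSet) - length(present)
  nNA <- if (length(present))
    rowSums(is.na(beta[, present, drop = FALSE])) else 0
  (nAbsent + nNA) / length(cpgSet) > maxMissingFrac
}

#' Estimate immune cell proportions by constrained projection
#'
#' Reference-based deconvolution: for every sample the beta values at the
#' shared marker CpGs are projected onto the reference signatures by
#' constrained least squares, minimising \code{||b - R' w||^2} over
#' \code{w >= 0} with either \code{sum(w) <= 1} (default; an unexplained
#' residual fraction is allowed) or \code{sum(w) = 1}. Samples failing the
#' >10\% missing-CpG rule are masked (all-NA row). The solver is an exact
#' active-set method on the 12-dimensional normal equations.
#'
#' @param beta A \linkS4class{MethylCohort}, or a samples x CpGs numeric
#'   matrix with CpG column names.
#' @param reference A \linkS4class{ReferenceLibrary}.
#' @param sumConstraint "le_one" (default) or "eq_one".
#' @param maxMissingFrac Masking threshold (default 0.10).
#' @param ... Unused.
#' @return A \linkS4class{CellProportions}.
#' @examples
#' ref <- generateReferenceLibrary(3, delta = 0.4, seed = 1)
#' ch <- generateCohort(20, bloodCompositionModel(), ref,
#'                      noisePrecision = Inf, seed = 2)
#' est <- estimateProportions(ch, ref)
#' max(abs(proportions(est) - trueProportions(ch)))  # exact recovery
#' @rdname estimateProportions
#' @export
setMethod("estimateProportions", signature("matrix", "ReferenceLibrary"),
  function(beta, reference, sumConstraint = c("le_one", "eq_one"),
           maxMissingFrac = 0.10, ...) {
    sumConstraint <- match.arg(sumConstraint)
    R <- meanBeta(reference)
    cells <- cellTypes(reference)
    lib <- colnames(R)
    shared <- intersect(lib, colnames(beta))
    if (length(reference@markerType)) {
      perCell <- table(factor(reference@markerType[match(shared, lib)],
                              levels = cells))
      if (any(perCell < 2L))
        stop("reference mismatch: fewer than 2 shared marker CpGs for: ",
             paste(names(perCell)[perCell < 2L], collapse = ", "))
    } else if (length(shared) < 2L * length(cells)) {
      stop("reference mismatch: too few shared marker CpGs")
    }
    Rs <- R[, shared, drop = FALSE]
    if (qr(Rs)$rank < nrow(Rs))
      stop("singular reference: rank-deficient on shared marker CpGs")

    masked <- applyLibraryMasking(beta, lib, maxMissingFrac)
    n <- nrow(beta)
    P <- matrix(NA_real_, n, length(cells),
                dimnames = list(rownames(beta), cells))
    resid <- rep(NA_real_, n)
    B <- beta[, shared, drop = FALSE]
    anyNA_ <- rowSums(is.na(B)) > 0L
    Gfull <- tcrossprod(Rs)
    for (i in seq_len(n)) {
      if (masked[i]) next
      b <- B[i, ]
      if (anyNA_[i]) {
        ok <- !is.na(b)
        Rv <- Rs[, ok, drop = FALSE]
        G <- tcrossprod(Rv)
        c0 <- drop(Rv %*% b[ok])
        bb <- sum(b[ok]^2)
        m <- sum(ok)
      } else {
        G <- Gfull
        c0 <- drop(Rs %*% b)
        bb <- sum(b^2)
        m <- length(b)
      }
      w <- solveProportions(G, c0, sumConstraint)
      P[i, ] <- w
      resid[i] <- sqrt(max(bb - 2 * sum(w * c0) + drop(t(w) %*% G %*% w),
                           0) / m)
    }
    new("CellProportions", proportions = P, fitResidual = resid,
        masked = masked, constraint = sumConstraint)
  })

#' @rdname estimateProportions
#' @export
setMethod("estimateProportions", signature("MethylCohort", "ReferenceLibrary"),
  function(beta, reference, sumConstraint = c("le_one", "eq_one"),
           maxMissingFrac = 0.10, ...) {
    estimateProportions(t(betaMatrix(beta)), reference,
                        sumConstraint = match.arg(sumConstraint),
                        maxMissingFrac = maxMissingFrac, ...)
  })
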