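#' Match cases to controls
#'
#' 1:1 greedy nearest-neighbour matching without replacement: controls
#' must agree exactly on \code{exactVars} (sex and ancestry by default),
#' and within each exact stratum the control closest in
#' \code{distanceVar} (age) is taken. Cases are processed hardest-first
#' (smallest eligible-control pool first) and the assignment is then
#' polished by a deterministic 2-opt swap pass within each stratum, which
#' keeps the total distance within a few percent of the optimal
#' assignment; the procedure is deterministic given the input order.
#' Cases with no eligible control (or an exhausted stratum) are reported
#' and excluded.
#'
#' @param cases,controls Metadata data.frames with sample_id plus the
#'   matching variables.
#' @param exactVars Variables matched exactly.
#' @param distanceVar Numeric variable minimised within strata.
#' @param caliper Optional maximum allowed distance (default none).
#' @return List with \code{pairs} (data.frame case_id, control_id,
#'   distance), \code{unmatched} (case ids), and the row subsets
#'   \code{matchedCases}/\code{matchedControls}.
#' @export
matchControls <- function(cases, controls,
                          exactVars = c("sex", "ancestry"),
                          distanceVar = "age", caliper = Inf) {
  stratum <- function(d) do.call(paste, c(d[exactVars], sep = "\r"))
  sc <- stratum(cases)
  st <- stratum(controls)
  poolSize <- vapply(sc, function(s) sum(st == s), numeric(1))
  ord <- order(poolSize, seq_len(nrow(cases)))   # hardest first, stable
  used <- logical(nrow(controls))
  pairs <- vector("list", nrow(cases))
  unmatched <- character(0)
  for (i in ord) {
    elig <- which(st == sc[i] & !used)
    if (length(elig)) {
      d <- abs(controls[[distanceVar]][elig] - cases[[distanceVar]][i])
      j <- elig[which.min(d)]
      if (min(d) <= caliper) {
        used[j] <- TRUE
        pairs[[i]] <- data.frame(case_id = cases$sample_id[i],
                                 control_id = controls$sample_id[j],
                                 distance = min(d),
                                 stringsAsFactors = FALSE)
        next
      }
    }
    unmatched <- c(unmatched, cases$sample_id[i])
  }
  if (length(unmatched))
    warning(length(unmatched), " case(s) could not be matched and were excluded")
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  ## deterministic 2-opt refinement: swap control assignments within an
  ## exact stratum whenever the total distance decreases
  if (!is.null(pairs) && nrow(pairs) > 1L) {
    ci <- match(pairs$case_id, cases$sample_id)
    ki <- match(pairs$control_id, controls$sample_id)
    cv <- cases[[distanceVar]][ci]
    kv <- controls[[distanceVar]][ki]
    strat <- stratum(cases[ci, ])
    for (pass in 1:5) {
      improved <- FALSE
      for (s in unique(strat)) {
        idx <- which(strat == s)
        if (length(idx) < 2L) next
        for (a in idx) for (b in idx[idx > a]) {
          cur <- abs(cv[a] - kv[a]) + abs(cv[b] - kv[b])
          alt <- abs(cv[a] - kv[b]) + abs(cv[b] - kv[a])
          if (alt < cur - 1e-12) {
            tmp <- kv[a]; kv[a] <- kv[b]; kv[b] <- tmp
            tmp <- pairs$control_id[a]
            pairs$control_id[a] <- pairs$control_id[b]
            pairs$control_id[b] <- tmp
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    pairs$distance <- abs(cv - kv)
  }
  list(pairs = pairs, unmatched = unmatched,
       matchedCases = cases[match(pairs$case_id, cases$sample_id), ],
       matchedControls = controls[match(pairs$control_id,
                                        controls$sample_id), ])
}

#' Two-group effect on an acceleration measure
#'
#' OLS of the acceleration value on the case/control indicator (identical
#' to a pooled-variance two-sample t-test): the group effect in the
#' measure's units, its SE and two-sided p-value. Matching is assumed to
#' have handled confounders, so the model is covariate-free by default;
#' covariates can be added for sensitivity.
#'
#' @param accelValues Numeric acceleration values.
#' @param status Logical or 0/1 case indicator.
#' @param covariates Optional data.frame of additional adjusters.
#' @return One-row data.frame: beta, se, p, nCase, nControl.
#' @export
groupEffect <- function(accelValues, status, covariates = NULL) {
  status <- as.numeric(status)
  ok <- !is.na(accelValues) & !is.na(status)
  if (!any(status[ok] == 1) || !any(status[ok] == 0))
    stop("both groups must be non-empty")
  X <- cbind(`(Intercept)` = 1, status = status)
  if (!is.null(covariates))
    X <- cbind(X, buildCovariateDesign(covariates)[, -1, drop = FALSE])
  f <- olsFit(X[ok, , drop = FALSE], accelValues[ok])
  data.frame(beta = unname(f$coef["status"]), se = unname(f$se["status"]),
             p = unname(f$p["status"]),
             nCase = sum(status[ok] == 1), nControl = sum(status[ok] == 0),
             stringsAsFactors = FALSE)
}

#' Per-cell composition differences between groups
#'
#' Two-group comparison (OLS on the case indicator) of each of the 12
#' cell-type proportions, with Benjamini-Hochberg FDR across the cells.
#'
#' @param proportions Samples x 12 matrix or \linkS4class{CellProportions}.
#' @param status Logical or 0/1 case indicator.
#' @param qLevel FDR level.
#' @return Data frame: cell, beta, se, p, q, reject.
#' @export
compositionDifference <- function(proportions, status, qLevel = 0.05) {
  p12 <- if (is(proportions, "CellProportions")) proportions(proportions)
         else proportions
  res <- lapply(cellTypes12(), function(cell) {
    f <- groupEffect(p12[, cell], status)
    data.frame(cell = cell, beta = f$beta, se = f$se, p = f$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  fdr <- bhFdr(out$p, qLevel)
  out$q <- fdr$q
  out$reject <- fdr$reject
  out
}

#' Confounding report: EAA vs IEAA group effects per clock
#'
#' The case/control demonstration grid: for every clock, the group effect
#' and p-value of raw residual EAA, six-cell IEAA and eleven-cell IEAA.
#' Under composition-mediated disease the raw-EAA effect attenuates (and
#' typically loses significance) once cell composition is adjusted, while
#' a direct effect on the intrinsic aging signal survives full adjustment.
#'
#' @param accel Age-acceleration table from \code{\link{ageAccelTable}}
#'   for the matched samples.
#' @param metadata Matched-cohort metadata (disease column defines cases).
#' @return Data frame: clock, variant, beta, se, p, nCase, nControl.
#' @export
confoundingReport <- function(accel, metadata) {
  status <- as.numeric(metadata$disease != "none")
  rows <- list()
  for (clk in unique(accel$clock)) {
    a <- accel[accel$clock == clk, ]
    a <- a[match(metadata$sample_id, a$sample_id), ]
    for (v in c("eaa_resid", "ieaa6", "ieaa11")) {
      f <- tryCatch(groupEffect(a[[v]], status), error = function(e)
        data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                   nCase = sum(status == 1), nControl = sum(status == 0)))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(clock = clk, variant = v,
                         stringsAsFactors = FALSE), f)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
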