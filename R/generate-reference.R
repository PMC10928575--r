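#' Generate a synthetic cell-type reference library
#'
#' Constructs a 12-cell-type reference of marker CpGs for simulation and
#' deconvolution. Each cell type receives \code{nCpgsPerType} marker CpGs
#' at which its mean beta exceeds every other cell type's by at least
#' \code{delta} (hypermethylated markers on a hypomethylated background),
#' which guarantees full row rank and a discriminating-marker margin.
#'
#' @param nCpgsPerType Number of marker CpGs per cell type (>= 2).
#' @param delta Discriminating margin in beta units (0 < delta <= 0.5).
#' @param precision Beta-noise concentration carried by the library for
#'   simulation (may be \code{Inf} for noiseless draws).
#' @param seed Integer seed; the construction is deterministic given it.
#' @return A \linkS4class{ReferenceLibrary}.
#' @examples
#' ref <- generateReferenceLibrary(nCpgsPerType = 3, delta = 0.4, seed = 1)
#' ref
#' @export
generateReferenceLibrary <- function(nCpgsPerType, delta = 0.35,
                                     precision = 100, seed = 1) {
  if (nCpgsPerType < 2L)
    stop("nCpgsPerType must be at least 2")
  if (delta <= 0 || delta > 0.5)
    stop("cannot embed margin: delta must lie in (0, 0.5]")
  cells <- cellTypes12()
  k <- length(cells)
  withSeed(seed, {
    nCpg <- k * nCpgsPerType
    m <- matrix(NA_real_, k, nCpg)
    markerType <- character(nCpg)
    cpgIds <- sprintf("cgM%04d", seq_len(nCpg))
    for (i in seq_len(k)) {
      cols <- (i - 1L) * nCpgsPerType + seq_len(nCpgsPerType)
      ## target cell high, all others at least delta lower
      hi <- stats::runif(nCpgsPerType, min = delta + 0.12, max = 0.95)
      for (j in seq_along(cols)) {
        lo <- stats::runif(k - 1L, min = 0.02, max = hi[j] - delta)
        m[-i, cols[j]] <- lo
        m[i, cols[j]] <- hi[j]
      }
      markerType[cols] <- cells[i]
    }
    dimnames(m) <- list(cells, cpgIds)
    new("ReferenceLibrary", cellTypes = cells, meanBeta = m,
        precision = precision, markerType = markerType)
  })
}
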