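# Shared small fixtures, built once per test run.
fixRef <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generateReferenceLibrary(3, delta = 0.35,
                                                       seed = 11)
    val
  }
})

fixDrift <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- makeDriftModel(20, 3e-4, seed = 11)
    val
  }
})

fixCohort <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- generateCohort(80, bloodCompositionModel(), fixRef(),
                             driftModel = fixDrift(), seed = 12)
    val
  }
})

# deterministic composition model (no stochastic terms) for exactness tests
detComposition <- function() bloodCompositionModel(dispersion = 0,
                                                   memoryAxisSd = 0)

# independent two-pass z-score oracle
zscoreOracle <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  (x - m) / s
}

# brute-force BH q-values: smallest level (on a grid) at which the
# step-up procedure rejects each p-value
bhBruteForce <- function(p, grid = seq(1e-4, 1, by = 1e-4)) {
  q <- rep(NA_real_, length(p))
  m <- length(p)
  for (alpha in grid) {
    srt <- sort(p)
    k <- which(srt <= seq_len(m) / m * alpha)
    rejected <- if (length(k)) p <= srt[max(k)] else rep(FALSE, m)
    q[is.na(q) & rejected] <- alpha
  }
  q[is.na(q)] <- 1
  q
}

# closed-form OLS via normal equations (independent of lm)
olsOracle <- function(X, y) {
  b <- solve(t(X) %*% X, t(X) %*% y)
  list(coef = drop(b), residuals = drop(y - X %*% b))
}
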