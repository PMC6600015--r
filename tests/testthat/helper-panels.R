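# Shared fixtures, built in code. Panels are cached per session so multiple
# test files can reuse them without regenerating.

.cache <- new.env(parent = emptyenv())

cachedPanel <- function(key, config) {
  if (is.null(.cache[[key]])) .cache[[key]] <- generatePanel(config)
  .cache[[key]]
}

# Default-sized panel (49 lines, 88 proteins, 2000 transcripts).
defaultPanel <- function(seed = 1L, effectSize = 2)
  cachedPanel(paste0("default_", seed, "_", effectSize),
              panelConfig(seed = seed, effectSize = effectSize))

# Small, fast panel for structural tests.
smallConfig <- function(seed = 7L, ...)
  panelConfig(nCellLines = 24L, nTranscripts = 150L, nProteins = 30L,
              nMutations = 60L, nDrugs = 6L,
              drugClasses = data.frame(size = 2L, shared = TRUE),
              nNullDrugs = 2L, seed = seed, ...)

smallPanel <- function(seed = 7L)
  cachedPanel(paste0("small_", seed), smallConfig(seed))

# Independent eigen-decomposition-based PLS reference: each component weight
# is the leading eigenvector of X' y y' X (with deflation between
# components), scores/loadings recomputed from scratch. Used only as an
# oracle against the NIPALS implementation.
eigenPLSReference <- function(X, y, ncomp) {
  Xd <- scale(X, scale = FALSE)
  yd <- y - mean(y)
  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    M <- crossprod(Xd, yd) %*% crossprod(yd, Xd)  # X'yy'X
    ev <- eigen(M, symmetric = TRUE)
    w <- ev$vectors[, 1]
    # fix sign to positive covariance with the response
    if (as.numeric(crossprod(w, crossprod(Xd, yd))) < 0) w <- -w
    tvec <- Xd %*% w
    tt <- sum(tvec^2)
    pl <- crossprod(Xd, tvec) / tt
    q <- sum(yd * tvec) / tt
    Xd <- Xd - tvec %*% t(pl)
    yd <- yd - q * tvec
    W[, a] <- w; P[, a] <- pl; Q[a] <- q; Tm[, a] <- tvec
  }
  B <- W %*% solve(crossprod(P, W), Q)
  list(W = W, P = P, Q = Q, scores = Tm, coefficients = B,
       predict = function(Xnew) {
         mean(y) + scale(Xnew, center = colMeans(X), scale = FALSE) %*% B
       })
}
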