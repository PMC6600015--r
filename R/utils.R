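#' @keywords internal
"_PACKAGE"

#' @useDynLib drugOmics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new is initialize setClass setGeneric setMethod setValidity validObject slot setClassUnion representation
#' @importFrom stats cor prcomp sd t.test p.adjust predict rnorm runif rbinom uniroot cov var coef approx setNames
#' @importFrom utils head read.csv read.delim write.csv write.table
NULL

## Deterministic named substream seeds: one master seed, independent streams per
## purpose, so e.g. adding drugs never perturbs transcript generation.
streamSeed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(as.character(name))) h <- (h * 31 + ch) %% 2147483647
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + h) %% 2147483647)
}

## Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Column-wise sample SD without apply() overhead.
colSds <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(NA_real_, ncol(x)))
  m <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * m^2, 0) / (n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Random partition of n items into k folds of near-equal size.
foldAssignment <- function(n, k, seed) {
  k <- min(k, n)
  withSeed(seed, sample(rep(seq_len(k), length.out = n)))
}

## Fast column-wise center/scale without sweep() overhead.
centerCols <- function(v, center) v - rep(center, each = nrow(v))

centerScaleCols <- function(v, center, scale) {
  nr <- nrow(v)
  (v - rep(center, each = nr)) / rep(scale, each = nr)
}
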