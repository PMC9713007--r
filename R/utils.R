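## Internal helpers shared across modules.

#' Derive a child seed from a parent seed and a named substream
#'
#' All randomness in the package descends from a single integer seed through
#' named substreams, so that changing the seed of one pipeline stage cannot
#' perturb another. The derivation hashes the stream name onto the parent
#' seed and keeps the result inside the portable 32-bit integer range.
#'
#' @param seed Parent integer seed.
#' @param stream Character scalar naming the substream (e.g. "nbs").
#' @param index Optional non-negative integer offset (e.g. subject index).
#' @return An integer seed in \[0, 2^31).
#' @export
childSeed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  ## sequential LCG mixing of (seed, stream hash, index): an affine
  ## combination would let nearby parent seeds alias each other's
  ## subject/permutation streams across simulations
  m <- 2147483647
  lcg <- function(x) (69069 * (x %% m) + 12345) %% m
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  x <- lcg(abs(as.numeric(seed)) %% m)
  x <- lcg((x + h) %% m)
  x <- lcg((x + as.numeric(index)) %% m)
  as.integer(x)
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Cholesky sampler for N(0, Sigma); rows are iid draws.
rmvnormChol <- function(n, sigma) {
  p <- ncol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  z %*% chol(sigma)
}

isSymmetricZeroDiag <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol && max(abs(diag(m))) <= tol
}

## Upper-triangle index helpers: edges are enumerated column-major over the
## strict upper triangle, the same order everywhere in the package.
upperTriIndex <- function(n) which(upper.tri(matrix(0, n, n)))

upperTriPairs <- function(n) {
  idx <- upperTriIndex(n)
  cbind(i = row(matrix(0, n, n))[idx], j = col(matrix(0, n, n))[idx])
}

## Rebuild a symmetric zero-diagonal matrix from its strict upper triangle.
symmetricFromUpper <- function(values, n, labels = NULL) {
  m <- matrix(0, n, n)
  m[upperTriIndex(n)] <- values
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

stopUnlessFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}
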