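## Connectome estimation: ridge (Tikhonov) regularized partial correlation,
## Fisher r-to-z, sparsity thresholding onto weighted graphs.

#' Ridge-regularized partial correlation matrix
#'
#' Columns are standardized to zero mean and unit variance, the sample
#' covariance (then a correlation matrix) is regularized as
#' `Theta = solve(Sigma + alpha * I)`, and partial correlations are read off
#' the precision as `rho_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)`. The
#' ridge term keeps the inversion stable when timepoints do not greatly
#' exceed the node count; with `alpha = 0` the estimate equals the classical
#' partial correlation (residual correlation after regressing each pair on
#' all remaining nodes).
#'
#' @param ts Timepoints-by-nodes numeric matrix (>= 2 of each).
#' @param alpha Non-negative ridge parameter; with 0 the sample covariance
#'   must be invertible (requires timepoints > nodes).
#' @return Symmetric partial-correlation matrix with zero diagonal,
#'   dimnames taken from `colnames(ts)`.
#' @export
tikhonovPartialCorrelation <- function(ts, alpha = 0.1) {
  ts <- as.matrix(ts)
  stopUnlessFinite(ts, "time series")
  stopifnot(nrow(ts) >= 2, ncol(ts) >= 2, length(alpha) == 1L, alpha >= 0)
  x <- scale(ts)
  if (any(!is.finite(x))) stop("constant column: cannot standardize to unit variance", call. = FALSE)
  s <- crossprod(x) / (nrow(x) - 1)
  sr <- s + diag(alpha, ncol(s))
  theta <- tryCatch(chol2inv(chol(sr)), error = function(e) NULL)
  if (is.null(theta)) {
    if (alpha == 0) {
      stop("sample covariance is singular at alpha = 0; use a positive ridge",
           call. = FALSE)
    }
    stop("regularized covariance not positive definite", call. = FALSE)
  }
  rho <- precisionToPartial(theta)
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- list(colnames(ts), colnames(ts))
  rho
}

#' Fisher r-to-z transform of a partial-correlation matrix
#'
#' `z = atanh(rho)` entrywise; the diagonal stays zero. Values within 1e-9
#' of +/-1 are clipped to magnitude 1 - 1e-12; larger violations are an
#' upstream contract error and fail loudly.
#'
#' @param rho Symmetric partial-correlation matrix, zero diagonal.
#' @param alpha Ridge parameter recorded in the result.
#' @param subjectID Subject identifier recorded in the result.
#' @return A [ConnectivityMatrix-class].
#' @export
fisherZ <- function(rho, alpha = NA_real_, subjectID = "subject") {
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  if (max(abs(rho[upper.tri(rho)])) > 1 + 1e-9) {
    stop("partial correlations with |rho| >= 1 beyond clipping tolerance",
         call. = FALSE)
  }
  near <- abs(rho) >= 1 - 1e-9
  rho2 <- ifelse(near, sign(rho) * (1 - 1e-12), rho)
  z <- atanh(rho2)
  diag(z) <- 0
  if (is.null(rownames(z))) {
    dimnames(z) <- list(sprintf("ROI%03d", seq_len(nrow(z))),
                        sprintf("ROI%03d", seq_len(nrow(z))))
  }
  new("ConnectivityMatrix", zValues = z, alpha = alpha, subjectID = subjectID)
}

#' Estimate the Fisher-z ridge connectome of one subject
#'
#' Convenience wrapper: [tikhonovPartialCorrelation()] followed by
#' [fisherZ()].
#'
#' @inheritParams tikhonovPartialCorrelation
#' @param subjectID Identifier recorded on the result.
#' @return A [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(ts, alpha = 0.1, subjectID = "subject") {
  fisherZ(tikhonovPartialCorrelation(ts, alpha), alpha = alpha,
          subjectID = subjectID)
}

#' Sparsity grid
#'
#' Arithmetic sequence `lo, lo+step, ..., hi` (inclusive), rounded to the
#' decimal precision of `step`. The conventional whole-brain grid is
#' `sparsityGrid(0.05, 0.40, 0.01)` (36 values).
#'
#' @param lo,hi Grid bounds in (0, 1], `lo <= hi`.
#' @param step Positive increment.
#' @return Numeric vector of sparsity values.
#' @export
sparsityGrid <- function(lo = 0.05, hi = 0.40, step = 0.01) {
  stopifnot(lo > 0, lo <= hi, hi <= 1, step > 0)
  k <- floor((hi - lo) / step + 1e-9)
  dec <- max(0, -floor(log10(step)) + 2)
  g <- round(lo + (0:k) * step, dec)
  if (!length(g)) stop("empty sparsity grid", call. = FALSE)
  g
}

#' Threshold a connectivity matrix onto a weighted graph at one sparsity
#'
#' Retains the `floor(s * N(N-1)/2)` strict-upper-triangle entries with the
#' largest signed Fisher-z values as undirected edges weighted by z (ties
#' broken by lexicographic node order). Every retained weight must be
#' strictly positive: the weighted metrics are defined for positive
#' couplings only, and a grid dense enough to pull in non-positive weights
#' is an error, not a silent drop.
#'
#' @param cm A [ConnectivityMatrix-class] (or plain symmetric matrix).
#' @param s Sparsity in (0, 1].
#' @return An [igraph][igraph::graph_from_data_frame] weighted undirected
#'   graph with graph attribute `sparsity`.
#' @export
thresholdBySparsity <- function(cm, s) {
  if (is(cm, "ConnectivityMatrix")) cm <- zValues(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (length(s) != 1L || s <= 0 || s > 1) stop("sparsity must lie in (0, 1]", call. = FALSE)
  n <- nrow(cm)
  labels <- rownames(cm)
  if (is.null(labels)) labels <- sprintf("ROI%03d", seq_len(n))
  m <- floor(s * n * (n - 1) / 2)
  pairs <- upperTriPairs(n)
  w <- cm[pairs]
  ord <- order(-w, pairs[, 1], pairs[, 2])
  keep <- ord[seq_len(m)]
  if (m > 0 && any(w[keep] <= 0)) {
    stop(sprintf("sparsity %.3g would retain non-positive weights; grid too dense for this matrix", s),
         call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = labels[pairs[keep, 1]], to = labels[pairs[keep, 2]],
               weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = labels))
  g <- igraph::set_graph_attr(g, "sparsity", s)
  g
}
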