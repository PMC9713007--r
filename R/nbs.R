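## Network-based statistic: edge-wise GLM t-maps over subjects' Fisher-z
## connectivity matrices, primary-threshold component extraction, and FWE
## inference on the largest-component size via Freedman-Lane permutation.
## The GLM is fit to all edges at once with matrix algebra, so the
## permutation loop is a handful of matrix products per permutation.

#' Build a GLM design for group inference
#'
#' Intercept + group indicator (patient = 1) + optional nuisance covariate
#' columns. The returned contrast selects the group effect.
#'
#' @param phenotypes data.frame with `group` (factor, second level = patient)
#'   and any covariate columns.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return List with `X` (design matrix), `contrast` vector and
#'   `nuisanceCols` (column indices of intercept + covariates).
#' @export
designMatrix <- function(phenotypes, covariates = character(0)) {
  grp <- phenotypes$group
  if (!is.factor(grp)) grp <- factor(grp)
  if (nlevels(grp) != 2) stop("group must have exactly two levels", call. = FALSE)
  X <- cbind(intercept = 1, group = as.numeric(grp == levels(grp)[2]))
  for (cv in covariates) {
    if (!cv %in% names(phenotypes)) stop("unknown covariate: ", cv, call. = FALSE)
    X <- cbind(X, as.numeric(phenotypes[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  contrast <- as.numeric(colnames(X) == "group")
  list(X = X, contrast = contrast,
       nuisanceCols = which(colnames(X) != "group"))
}

## Vectorized OLS t-statistics of c'beta for a response matrix Y (n x m).
## Returns list(t = length-m vector, df). Zero-residual-variance columns
## are flagged t = 0 (degenerate, no information about error variance).
.glmTStats <- function(X, Y, contrast) {
  n <- nrow(X); p <- ncol(X)
  xtxInv <- chol2inv(chol(crossprod(X)))
  H <- xtxInv %*% t(X)
  beta <- H %*% Y
  resid <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  cb <- as.numeric(contrast %*% beta)
  cvc <- as.numeric(t(contrast) %*% xtxInv %*% contrast)
  se <- sqrt(sigma2 * cvc)
  t <- ifelse(se > 0, cb / se, 0)
  list(t = t, df = df, degenerate = which(se == 0))
}

#' Edge-wise GLM t-statistic matrix
#'
#' Fits the same ordinary-least-squares GLM to every strict-upper-triangle
#' edge of the stacked Fisher-z matrices and returns the symmetric matrix
#' of contrast t-statistics (`t = c'beta / sqrt(sigma2 c'(X'X)^-1 c)`).
#' Edges with zero residual variance get t = 0 and are reported in the
#' `degenerateEdges` attribute.
#'
#' @param stack List of [ConnectivityMatrix-class] objects sharing node
#'   labels, aligned with the design rows.
#' @param design A [designMatrix()] list.
#' @return Symmetric t matrix (zero diagonal) with attributes `df` and
#'   `degenerateEdges`.
#' @export
edgewiseGLM <- function(stack, design) {
  Y <- .stackUpperTri(stack)
  if (nrow(design$X) != nrow(Y)) stop("design rows must match subject count", call. = FALSE)
  if (nrow(Y) < ncol(design$X) + 1) stop("fewer subjects than regressors + 1", call. = FALSE)
  fit <- .glmTStats(design$X, Y, design$contrast)
  labels <- nodeLabels(stack[[1]])
  tm <- symmetricFromUpper(fit$t, length(labels), labels)
  attr(tm, "df") <- fit$df
  attr(tm, "degenerateEdges") <- fit$degenerate
  tm
}

## Stack the strict upper triangles of the z matrices into subjects x edges.
.stackUpperTri <- function(stack) {
  labels <- nodeLabels(stack[[1]])
  idx <- upperTriIndex(length(labels))
  Y <- t(vapply(stack, function(cm) {
    if (!identical(nodeLabels(cm), labels))
      stop("connectivity matrices have mismatched node labels", call. = FALSE)
    zValues(cm)[idx]
  }, numeric(length(idx))))
  Y
}

#' Connected components of suprathreshold edges
#'
#' Forms a graph from the edges with `t > tCrit` and returns its connected
#' components sorted by edge count (descending). Component size is measured
#' in edges (the NBS extent convention); the node set is reported alongside.
#'
#' @param tMatrix Symmetric t matrix (e.g. from [edgewiseGLM()]).
#' @param tCrit Positive primary threshold on t.
#' @return List of components: each has `edges` (two-column label matrix),
#'   `nodes` and `nEdges`. Empty list when nothing survives.
#' @export
suprathresholdComponents <- function(tMatrix, tCrit) {
  stopifnot(tCrit > 0)
  n <- nrow(tMatrix)
  labels <- rownames(tMatrix)
  if (is.null(labels)) labels <- sprintf("ROI%03d", seq_len(n))
  pairs <- upperTriPairs(n)
  keep <- tMatrix[pairs] > tCrit
  if (!any(keep)) return(list())
  ep <- pairs[keep, , drop = FALSE]
  memb <- .unionFindComponents(ep, n)
  comps <- split(seq_len(nrow(ep)), memb[ep[, 1]])
  out <- lapply(comps, function(rows) {
    e <- ep[rows, , drop = FALSE]
    list(edges = cbind(labels[e[, 1]], labels[e[, 2]]),
         nodes = labels[sort(unique(as.vector(e)))],
         nEdges = length(rows))
  })
  out[order(-vapply(out, function(co) co$nEdges, numeric(1)))]
}

## Union-find over an edge list; returns component id per node.
.unionFindComponents <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

## Max suprathreshold component size (edges) from a t vector over edges.
.maxComponentSize <- function(tVec, tCrit, pairs, n) {
  keep <- tVec > tCrit
  if (!any(keep)) return(0L)
  ep <- pairs[keep, , drop = FALSE]
  memb <- .unionFindComponents(ep, n)
  max(tabulate(memb[ep[, 1]]))
}

#' Network-based statistic permutation test
#'
#' Edge-wise GLM, primary thresholding at the one-sided upper t quantile of
#' `pPrimary`, component extraction, and family-wise inference on the
#' largest-component size (in edges) under Freedman-Lane permutation: the
#' nuisance-only reduced model is fit once, its residuals are permuted and
#' added back to the reduced fit, and the full model is refit on the
#' pseudo-responses. With no nuisance covariates the reduced model is the
#' intercept alone.
#'
#' @param stack List of [ConnectivityMatrix-class] objects.
#' @param design A [designMatrix()] list.
#' @param pPrimary Primary edge-level p threshold (one-sided), in (0, 0.5].
#' @param nPerm Number of permutations (>= 1).
#' @param direction `"positive"` (patient > control under the default
#'   contrast) or `"negative"` (contrast negated).
#' @param seed Integer seed for the permutations.
#' @param paperConvention If TRUE, p = count/nPerm; default is the
#'   +1-corrected `(1 + count) / (nPerm + 1)`, which can never be zero.
#' @return An [NBSResult-class].
#' @export
nbsTest <- function(stack, design, pPrimary = 0.001, nPerm = 5000L,
                    direction = c("positive", "negative"), seed = 1L,
                    paperConvention = FALSE) {
  direction <- match.arg(direction)
  stopifnot(pPrimary > 0, pPrimary <= 0.5, nPerm >= 1)
  contrast <- design$contrast
  if (direction == "negative") contrast <- -contrast
  Y <- .stackUpperTri(stack)
  X <- design$X
  n <- nrow(Y)
  labels <- nodeLabels(stack[[1]])
  nNodes <- length(labels)
  pairs <- upperTriPairs(nNodes)
  obs <- .glmTStats(X, Y, contrast)
  tCrit <- qt(1 - pPrimary, obs$df)
  tm <- symmetricFromUpper(obs$t, nNodes, labels)
  comps <- suprathresholdComponents(tm, tCrit)
  ## Freedman-Lane: reduced (nuisance-only) fit, permute residuals
  Z <- X[, design$nuisanceCols, drop = FALSE]
  ztzInv <- chol2inv(chol(crossprod(Z)))
  fitted <- Z %*% (ztzInv %*% crossprod(Z, Y))
  residR <- Y - fitted
  nullMax <- numeric(nPerm)
  withSeed(childSeed(seed, "nbs-perm"), {
    for (b in seq_len(nPerm)) {
      Yb <- fitted + residR[sample.int(n), , drop = FALSE]
      tb <- .glmTStats(X, Yb, contrast)$t
      nullMax[b] <- .maxComponentSize(tb, tCrit, pairs, nNodes)
    }
  })
  if (nPerm < 20) warning("permutation count too small for p < 0.05")
  comps <- lapply(comps, function(co) {
    count <- sum(nullMax >= co$nEdges)
    co$pPerm <- if (paperConvention) count / nPerm else (1 + count) / (nPerm + 1)
    co
  })
  new("NBSResult", direction = direction, pPrimary = pPrimary,
      tCritical = tCrit, components = comps, nullMaxSize = nullMax,
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}
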