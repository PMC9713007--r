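## Group inference on AUC topological features: max-statistic permutation
## GLM with Freedman-Lane permutation, and Pearson partial correlation with
## clinical variables, Bonferroni-adjusted.

#' Max-statistic permutation GLM over AUC features
#'
#' Fits the group-contrast GLM to every feature, then builds a family-wise
#' null by Freedman-Lane permutation: per permutation the maximum |t| is
#' recorded within each family, and each feature's FWE p value is the
#' +1-corrected exceedance rate of its family's max-statistic null at the
#' observed |t|. Tests are two-sided. By default each global attribute is
#' its own (singleton) family and each nodal attribute forms one family
#' across all ROIs.
#'
#' @param features SummarizedExperiment from [assembleAucFeatures()], or a
#'   features-by-subjects matrix.
#' @param design A [designMatrix()] list aligned with the subjects.
#' @param family Named character vector mapping each feature to its family
#'   label; NULL uses the default partition above (attribute-wise).
#' @param nPerm Number of permutations.
#' @param seed Integer seed.
#' @return A [PermGLMResult-class].
#' @export
maxstatPermGLM <- function(features, design, family = NULL, nPerm = 5000L,
                           seed = 1L) {
  mat <- if (is(features, "SummarizedExperiment")) assay(features, "auc") else features
  stopifnot(is.matrix(mat), nPerm >= 1)
  Y <- t(mat)                       # subjects x features
  if (nrow(design$X) != nrow(Y)) stop("design rows must match subjects", call. = FALSE)
  featNames <- colnames(Y)
  if (is.null(family)) {
    family <- if (is(features, "SummarizedExperiment")) {
      setNames(rowData(features)$attribute, featNames)
    } else {
      setNames(featNames, featNames)  # every feature its own family
    }
  }
  if (!all(featNames %in% names(family)))
    stop("family must cover every feature", call. = FALSE)
  family <- family[featNames]
  X <- design$X
  obs <- .glmTStats(X, Y, design$contrast)
  tObs <- setNames(obs$t, featNames)
  famLevels <- unique(family)
  famIdx <- lapply(famLevels, function(f) which(family == f))
  names(famIdx) <- famLevels
  Z <- X[, design$nuisanceCols, drop = FALSE]
  ztzInv <- chol2inv(chol(crossprod(Z)))
  fitted <- Z %*% (ztzInv %*% crossprod(Z, Y))
  residR <- Y - fitted
  n <- nrow(Y)
  nullMax <- matrix(0, nPerm, length(famLevels),
                    dimnames = list(NULL, famLevels))
  withSeed(childSeed(seed, "maxstat-perm"), {
    for (b in seq_len(nPerm)) {
      Yb <- fitted + residR[sample.int(n), , drop = FALSE]
      tb <- abs(.glmTStats(X, Yb, design$contrast)$t)
      nullMax[b, ] <- vapply(famIdx, function(ix) max(tb[ix]), numeric(1))
    }
  })
  pPerm <- vapply(seq_along(tObs), function(k) {
    nm <- nullMax[, family[k]]
    (1 + sum(nm >= abs(tObs[k]))) / (nPerm + 1)
  }, numeric(1))
  new("PermGLMResult", tObserved = tObs, pPerm = setNames(pPerm, featNames),
      family = family, nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Pearson partial correlation controlling for covariates
#'
#' Correlates the residuals of `x` and `y` after regressing each on an
#' intercept plus the covariate columns; the p value comes from the t
#' distribution with `n - k - 2` degrees of freedom (k covariates).
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Numeric matrix/data.frame of covariates (or NULL for a
#'   plain Pearson correlation).
#' @return List with `r`, `p`, `df`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2) stop("need n > number of covariates + 2", call. = FALSE)
  Z <- cbind(rep(1, n), if (k > 0) as.matrix(covariates))
  rx <- lm.fit(Z, x)$residuals
  ry <- lm.fit(Z, y)$residuals
  ## numerically-zero residuals (constant or covariate-collinear input)
  if (sd(rx) <= 1e-12 * max(1, sd(x)) || sd(ry) <= 1e-12 * max(1, sd(y)))
    stop("zero residual variance", call. = FALSE)
  r <- cor(rx, ry)
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tval), df)
  list(r = r, p = p, df = df)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)` with m the number of tests (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Vector of raw p values in \[0, 1\].
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Clinical partial-correlation table
#'
#' Partial correlation of each selected AUC feature with each clinical
#' variable, controlling for nuisance covariates, with a single Bonferroni
#' correction over the full (attribute x clinical variable) grid of tests.
#'
#' @param features SummarizedExperiment from [assembleAucFeatures()].
#' @param featureNames Features (rows) to test.
#' @param clinicalVars Clinical phenotype columns to correlate with.
#' @param controlVars Phenotype columns to control for.
#' @param subjects Optional subject subset (e.g. the patient group only,
#'   as clinical scores are typically collected for patients).
#' @return data.frame: attribute, clinical, r, p, p_bonferroni, df.
#' @export
clinicalCorrelations <- function(features, featureNames, clinicalVars,
                                 controlVars = character(0), subjects = NULL) {
  mat <- assay(features, "auc")
  pheno <- as.data.frame(colData(features))
  if (!is.null(subjects)) {
    keep <- colnames(mat) %in% subjects
    mat <- mat[, keep, drop = FALSE]
    pheno <- pheno[keep, , drop = FALSE]
  }
  covs <- if (length(controlVars)) as.matrix(pheno[, controlVars, drop = FALSE]) else NULL
  rows <- expand.grid(attribute = featureNames, clinical = clinicalVars,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(k) {
    pc <- partialCorrelation(mat[rows$attribute[k], ],
                             pheno[[rows$clinical[k]]], covs)
    data.frame(rows[k, ], r = pc$r, p = pc$p, df = pc$df)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- bonferroni(out$p, m = nrow(out))
  rownames(out) <- NULL
  out[, c("attribute", "clinical", "r", "p", "p_bonferroni", "df")]
}
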