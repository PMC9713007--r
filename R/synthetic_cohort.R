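## Synthetic two-group cohort generator. Group differences are planted on
## the partial-correlation scale in the precision matrices, so every
## downstream stage (connectome estimation, NBS, classification) has exact
## ground truth.

#' Configuration for a synthetic two-group cohort
#'
#' Defaults mirror the study design the package targets: two groups of 46
#' male subjects, ROI time series of 196 retained volumes, and nuisance
#' covariates (age, education, nicotine-dependence score) plus clinical
#' scores (anxiety, psychiatric-symptom ratings) with group means and
#' spreads matching that cohort. The node count defaults to the 246-region
#' whole-brain parcellation; tests and examples pass smaller values.
#'
#' @param nPerGroup Subjects per group (>= 2).
#' @param nNodes Number of ROIs (>= 4).
#' @param nTimepoints Timepoints per subject.
#' @param baseDensity Fraction of nonzero off-diagonal entries in the shared
#'   backbone precision matrix.
#' @param plantedEdges data.frame (or NULL) with columns `i`, `j`, `delta`:
#'   node indices and the signed target partial-correlation difference
#'   (group2 - group1) planted on that edge.
#' @param arCoeff Lag-1 temporal autocorrelation in \[0, 1).
#' @param covariateSpec Named list of lists `list(mean=, sd=)` describing
#'   Gaussian nuisance covariates drawn per subject.
#' @param clinicalSpec Named list of lists `list(mean=, sd=, beta=)`:
#'   each clinical score is `mean + beta * z(summary) + N(0, sd)`, where
#'   `summary` is the subject's mean ridge partial correlation over the
#'   planted edges (mean absolute off-diagonal partial correlation when no
#'   edges are planted), standardized across the cohort.
#' @param seed Integer RNG seed.
#' @return A validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nPerGroup = 46L, nNodes = 246L, nTimepoints = 196L,
                         baseDensity = 0.1, plantedEdges = NULL,
                         arCoeff = 0.3,
                         covariateSpec = list(
                           age = list(mean = 34.4, sd = 8.9),
                           education = list(mean = 13.3, sd = 4.0),
                           ftnd = list(mean = 6.0, sd = 2.7)),
                         clinicalSpec = list(
                           hama = list(mean = 22.4, sd = 8.6, beta = 0),
                           bprs = list(mean = 39.1, sd = 11.1, beta = 0)),
                         seed = 1L) {
  if (is.null(plantedEdges)) {
    plantedEdges <- data.frame(i = integer(0), j = integer(0), delta = numeric(0))
  }
  plantedEdges <- as.data.frame(plantedEdges)
  cfg <- list(nPerGroup = as.integer(nPerGroup), nNodes = as.integer(nNodes),
              nTimepoints = as.integer(nTimepoints), baseDensity = baseDensity,
              plantedEdges = plantedEdges, arCoeff = arCoeff,
              covariateSpec = covariateSpec, clinicalSpec = clinicalSpec,
              seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  stopifnot(cfg$nPerGroup >= 2L, cfg$nNodes >= 4L, cfg$nTimepoints >= 2L,
            cfg$baseDensity > 0, cfg$baseDensity <= 1,
            cfg$arCoeff >= 0, cfg$arCoeff < 1)
  pe <- cfg$plantedEdges
  if (nrow(pe)) {
    stopifnot(all(c("i", "j", "delta") %in% names(pe)))
    if (any(pe$i == pe$j)) stop("planted edges must join distinct nodes")
    if (any(pe$i < 1 | pe$i > cfg$nNodes | pe$j < 1 | pe$j > cfg$nNodes))
      stop("planted edge indices out of range")
    key <- paste(pmin(pe$i, pe$j), pmax(pe$i, pe$j))
    if (anyDuplicated(key)) stop("duplicate planted edges")
  }
  invisible(cfg)
}

#' Build the two group precision matrices with planted differences
#'
#' Starts from a shared sparse backbone precision (random graph support with
#' constant off-diagonal magnitude and random sign), edits the planted
#' off-diagonal entries of group 2 so that the implied partial correlation
#' `-Theta_ij / sqrt(Theta_ii Theta_jj)` differs from group 1's by exactly
#' `delta`, and diagonally loads BOTH matrices by the same `tau * I` until
#' both are positive definite. Loading both groups identically keeps every
#' off-planted partial correlation bitwise identical between the groups, and
#' the planted edits are re-derived from the loaded diagonal at each
#' iteration so the planted differences remain exact.
#'
#' @param config A [cohortConfig()].
#' @return List with SPD matrices `theta1`, `theta2` and the `tau` applied.
#' @export
buildGroupPrecisions <- function(config) {
  validateCohortConfig(config)
  n <- config$nNodes
  pe <- config$plantedEdges
  withSeed(childSeed(config$seed, "precision"), {
    ## backbone: random support, constant magnitude 0.2, random sign
    nPairs <- n * (n - 1) / 2
    support <- runif(nPairs) < config$baseDensity
    vals <- ifelse(support, 0.2 * sign(runif(nPairs) - 0.5), 0)
    theta0 <- symmetricFromUpper(vals, n)
    diag(theta0) <- 1
    ## make sure planted edges exist in the backbone of group 1 with a
    ## definite value, so deltas act on a known base
    if (nrow(pe)) {
      for (k in seq_len(nrow(pe))) {
        i <- pe$i[k]; j <- pe$j[k]
        if (theta0[i, j] == 0) theta0[i, j] <- theta0[j, i] <- -0.1
      }
    }
    tau <- 0
    step <- 0.25
    for (iter in 1:60) {
      theta1 <- theta0
      diag(theta1) <- diag(theta0) + tau
      theta2 <- theta1
      ok <- TRUE
      for (k in seq_len(nrow(pe))) {
        i <- pe$i[k]; j <- pe$j[k]
        dd <- sqrt(theta1[i, i] * theta1[j, j])
        rho1 <- -theta1[i, j] / dd
        rho2 <- rho1 + pe$delta[k]
        if (abs(rho2) >= 1) {
          stop(sprintf("planted edge (%d, %d): target partial correlation %.3f out of (-1, 1)",
                       i, j, rho2), call. = FALSE)
        }
        theta2[i, j] <- theta2[j, i] <- -rho2 * dd
      }
      e1 <- min(eigen(theta1, symmetric = TRUE, only.values = TRUE)$values)
      e2 <- if (nrow(pe)) min(eigen(theta2, symmetric = TRUE, only.values = TRUE)$values) else e1
      if (e1 > 1e-4 && e2 > 1e-4) {
        return(list(theta1 = theta1, theta2 = theta2, tau = tau))
      }
      tau <- tau + step
    }
  })
  stop("could not reach positive definiteness by diagonal loading", call. = FALSE)
}

#' Simulate one subject's ROI time series from a precision matrix
#'
#' Draws a stationary zero-mean Gaussian AR(1) series whose contemporaneous
#' covariance equals `solve(precision)` exactly: the first row is drawn from
#' N(0, Sigma) and subsequent rows follow `x_t = phi x_{t-1} + e_t` with
#' innovations `e_t ~ N(0, (1 - phi^2) Sigma)`, so the AR filtering does not
#' distort the target covariance.
#'
#' @param precision SPD precision matrix.
#' @param nTimepoints Number of rows to draw.
#' @param arCoeff Lag-1 autocorrelation phi in \[0, 1).
#' @param seed Integer seed.
#' @return `nTimepoints x nNodes` numeric matrix.
#' @export
simulateSubject <- function(precision, nTimepoints, arCoeff = 0, seed = 1L) {
  stopifnot(arCoeff >= 0, arCoeff < 1, nTimepoints >= 2)
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision matrix is not positive definite", call. = FALSE)
  sigma <- chol2inv(chol(precision))
  sigma <- (sigma + t(sigma)) / 2
  withSeed(seed, {
    cs <- chol(sigma)
    p <- ncol(sigma)
    x <- matrix(0, nTimepoints, p)
    x[1, ] <- rnorm(p) %*% cs
    if (nTimepoints > 1) {
      innov <- matrix(rnorm((nTimepoints - 1) * p), nTimepoints - 1, p) %*%
        (sqrt(1 - arCoeff^2) * cs)
      for (t in 2:nTimepoints) {
        x[t, ] <- arCoeff * x[t - 1, ] + innov[t - 1, ]
      }
    }
    x
  })
}

#' Simulate a full two-group cohort
#'
#' Generates per-subject time series from the two group precisions, Gaussian
#' nuisance covariates, and clinical scores linked (via `beta` in the
#' clinical spec) to each subject's planted-edge connectivity summary.
#'
#' @param config A [cohortConfig()].
#' @return A [Cohort-class] object.
#' @export
simulateCohort <- function(config) {
  validateCohortConfig(config)
  prec <- buildGroupPrecisions(config)
  nTot <- 2L * config$nPerGroup
  ids <- sprintf("sub-%03d", seq_len(nTot))
  group <- factor(rep(c("control", "patient"), each = config$nPerGroup),
                  levels = c("control", "patient"))
  series <- vector("list", nTot)
  names(series) <- ids
  for (s in seq_len(nTot)) {
    theta <- if (group[s] == "control") prec$theta1 else prec$theta2
    series[[s]] <- simulateSubject(theta, config$nTimepoints, config$arCoeff,
                                   seed = childSeed(config$seed, "subject", s))
    colnames(series[[s]]) <- sprintf("ROI%03d", seq_len(config$nNodes))
  }
  pheno <- data.frame(subject_id = ids, group = group, stringsAsFactors = FALSE)
  withSeed(childSeed(config$seed, "covariates"), {
    for (nm in names(config$covariateSpec)) {
      sp <- config$covariateSpec[[nm]]
      pheno[[nm]] <- round(rnorm(nTot, sp$mean, sp$sd), 2)
    }
  })
  ## network summary feeding the clinical scores: mean ridge partial
  ## correlation over planted edges (mean |rho| off-diagonal if none)
  summ <- vapply(series, function(x) {
    rho <- tikhonovPartialCorrelation(x, alpha = 0.1)
    if (nrow(config$plantedEdges)) {
      mean(rho[cbind(config$plantedEdges$i, config$plantedEdges$j)])
    } else {
      mean(abs(rho[upper.tri(rho)]))
    }
  }, numeric(1))
  zsumm <- if (sd(summ) > 0) (summ - mean(summ)) / sd(summ) else summ * 0
  withSeed(childSeed(config$seed, "clinical"), {
    for (nm in names(config$clinicalSpec)) {
      sp <- config$clinicalSpec[[nm]]
      pheno[[nm]] <- round(sp$mean + sp$beta * zsumm + rnorm(nTot, 0, sp$sd), 2)
    }
  })
  rownames(pheno) <- NULL
  new("Cohort", series = series, phenotypes = pheno,
      groundTruth = list(theta1 = prec$theta1, theta2 = prec$theta2,
                         tau = prec$tau,
                         planted_edges = config$plantedEdges,
                         network_summary = summ,
                         seed = config$seed))
}

#' Write a cohort to disk as plain-text files
#'
#' One TSV per subject (timepoints x ROIs, header = ROI labels), one
#' phenotype CSV, and a ground-truth JSON (planted edges, deltas, seed).
#'
#' @param cohort A [Cohort-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsDir <- file.path(dir, "timeseries")
  dir.create(tsDir, showWarnings = FALSE)
  for (id in names(timeSeries(cohort))) {
    write.table(format(timeSeries(cohort)[[id]], digits = 10, trim = TRUE),
                file.path(tsDir, paste0(id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(phenotypes(cohort), file.path(dir, "phenotypes.csv"),
              sep = ",", quote = FALSE, row.names = FALSE)
  gt <- groundTruth(cohort)
  jsonlite::write_json(
    list(planted_edges = gt$planted_edges, seed = gt$seed, tau = gt$tau),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Analytic partial correlations implied by a precision matrix
#'
#' `rho_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)`, zero diagonal.
#'
#' @param theta SPD precision matrix.
#' @return Symmetric partial-correlation matrix.
#' @export
precisionToPartial <- function(theta) {
  d <- sqrt(diag(theta))
  rho <- -theta / tcrossprod(d)
  diag(rho) <- 0
  rho
}
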