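## Central S4 containers. Result classes are lightweight records with
## validity checks and show() methods; the AUC feature table is a
## SummarizedExperiment (features x subjects) built in graph_metrics.R.

#' ConnectivityMatrix: Fisher-z partial-correlation connectome of one subject
#'
#' Symmetric node-by-node matrix of Fisher r-to-z transformed ridge partial
#' correlations with a zero diagonal, together with the ridge parameter used
#' and the subject identifier.
#'
#' @slot zValues Symmetric numeric matrix (nodes x nodes), zero diagonal,
#'   dimnames carry the ROI labels.
#' @slot alpha Ridge (Tikhonov) regularization parameter used.
#' @slot subjectID Subject identifier.
#' @export
setClass("ConnectivityMatrix",
  representation(zValues = "matrix", alpha = "numeric", subjectID = "character"),
  validity = function(object) {
    z <- object@zValues
    if (!is.numeric(z) || nrow(z) != ncol(z)) return("zValues must be square numeric")
    if (!all(is.finite(z))) return("zValues must be finite")
    if (!isSymmetricZeroDiag(z, tol = 1e-8)) return("zValues must be symmetric with zero diagonal")
    if (is.null(rownames(z)) || anyDuplicated(rownames(z))) return("node labels must be unique dimnames")
    if (length(object@alpha) != 1L || (!is.na(object@alpha) && object@alpha < 0))
      return("alpha must be a single non-negative number (or NA if unknown)")
    TRUE
  }
)

#' @describeIn ConnectivityMatrix Fisher-z matrix accessor
#' @param object A `ConnectivityMatrix`.
#' @export
setGeneric("zValues", function(object) standardGeneric("zValues"))
#' @rdname ConnectivityMatrix
#' @export
setMethod("zValues", "ConnectivityMatrix", function(object) object@zValues)

#' @describeIn ConnectivityMatrix node (ROI) labels
#' @export
setGeneric("nodeLabels", function(object) standardGeneric("nodeLabels"))
#' @rdname ConnectivityMatrix
#' @export
setMethod("nodeLabels", "ConnectivityMatrix", function(object) rownames(object@zValues))

#' @describeIn ConnectivityMatrix subject identifier
#' @export
setGeneric("subjectID", function(object) standardGeneric("subjectID"))
#' @rdname ConnectivityMatrix
#' @export
setMethod("subjectID", "ConnectivityMatrix", function(object) object@subjectID)

setMethod("show", "ConnectivityMatrix", function(object) {
  cat("ConnectivityMatrix:", object@subjectID, "\n",
      " nodes:", nrow(object@zValues),
      " alpha:", object@alpha,
      " |z| range:", sprintf("[%.3g, %.3g]",
        min(abs(object@zValues[upper.tri(object@zValues)])),
        max(abs(object@zValues))), "\n")
})

#' Cohort: a simulated two-group collection of ROI time series
#'
#' @slot series Named list of timepoints-by-nodes matrices, one per subject.
#' @slot phenotypes data.frame with subject_id, group and covariate/clinical
#'   columns, rows aligned with `series`.
#' @slot groundTruth List with the two group precision matrices, the planted
#'   edge table and the seed used.
#' @export
setClass("Cohort",
  representation(series = "list", phenotypes = "data.frame", groundTruth = "list"),
  validity = function(object) {
    if (length(object@series) != nrow(object@phenotypes))
      return("series and phenotypes must have one entry per subject")
    if (!identical(names(object@series), object@phenotypes$subject_id))
      return("series names must match phenotype subject_id order")
    dims <- vapply(object@series, dim, integer(2))
    if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L)
      return("all subjects must share timepoint and node counts")
    if (!all(vapply(object@series, function(m) all(is.finite(m)), logical(1))))
      return("time series must be finite")
    TRUE
  }
)

#' @describeIn Cohort list of per-subject time-series matrices
#' @param object A `Cohort`.
#' @export
setGeneric("timeSeries", function(object) standardGeneric("timeSeries"))
#' @rdname Cohort
#' @export
setMethod("timeSeries", "Cohort", function(object) object@series)

#' @describeIn Cohort phenotype table
#' @export
setGeneric("phenotypes", function(object) standardGeneric("phenotypes"))
#' @rdname Cohort
#' @export
setMethod("phenotypes", "Cohort", function(object) object@phenotypes)

#' @describeIn Cohort ground-truth precision matrices and planted edges
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname Cohort
#' @export
setMethod("groundTruth", "Cohort", function(object) object@groundTruth)

setMethod("show", "Cohort", function(object) {
  d <- dim(object@series[[1]])
  cat("Cohort:", length(object@series), "subjects (",
      paste(table(object@phenotypes$group), collapse = " vs "), "),",
      d[2], "nodes x", d[1], "timepoints\n",
      " planted edges:", nrow(object@groundTruth$planted_edges), "\n")
})

#' NBSResult: network-based statistic inference outcome
#'
#' @slot direction "positive" or "negative" contrast direction.
#' @slot pPrimary Primary edge-level p threshold.
#' @slot tCritical Implied one-sided t critical value.
#' @slot components List of suprathreshold components; each has `edges`
#'   (two-column label matrix), `nodes`, `nEdges`, `pPerm`.
#' @slot nullMaxSize Numeric vector: permutation null of the largest
#'   component size (edges).
#' @slot nPerm Number of permutations.
#' @slot seed Seed used for the permutations.
#' @export
setClass("NBSResult",
  representation(direction = "character", pPrimary = "numeric",
                 tCritical = "numeric", components = "list",
                 nullMaxSize = "numeric", nPerm = "integer", seed = "integer"),
  validity = function(object) {
    ps <- vapply(object@components, function(co) co$pPerm, numeric(1))
    if (length(ps) && (any(ps < 0) || any(ps > 1)))
      return("component pPerm must lie in [0, 1] (0 only under the raw count convention)")
    ne <- vapply(object@components, function(co) co$nEdges, numeric(1))
    if (length(ne) && any(ne < 1)) return("components must contain at least one edge")
    TRUE
  }
)

setMethod("show", "NBSResult", function(object) {
  cat("NBSResult (", object@direction, " direction): ",
      length(object@components), " suprathreshold component(s), ",
      object@nPerm, " permutations\n", sep = "")
  for (co in head(object@components, 5)) {
    cat(sprintf("  %d edges / %d nodes, p_perm = %.4g\n",
                co$nEdges, length(co$nodes), co$pPerm))
  }
})

#' PermGLMResult: max-statistic permutation GLM over AUC features
#'
#' @slot tObserved Named numeric vector of observed contrast t statistics.
#' @slot pPerm Named numeric vector of family-wise permutation p values.
#' @slot family Named character vector mapping feature -> family label.
#' @slot nPerm Number of permutations.
#' @slot seed Seed used.
#' @export
setClass("PermGLMResult",
  representation(tObserved = "numeric", pPerm = "numeric",
                 family = "character", nPerm = "integer", seed = "integer"),
  validity = function(object) {
    if (any(object@pPerm <= 0 | object@pPerm > 1)) return("pPerm must lie in (0, 1]")
    if (!identical(names(object@tObserved), names(object@pPerm)))
      return("tObserved and pPerm must be aligned")
    TRUE
  }
)

setMethod("show", "PermGLMResult", function(object) {
  cat("PermGLMResult:", length(object@tObserved), "features,",
      length(unique(object@family)), "families,", object@nPerm, "permutations\n")
  sig <- sum(object@pPerm < 0.05)
  cat("  features with p_perm < 0.05:", sig, "\n")
})

#' ClassifierReport: repeated cross-validated SVM performance
#'
#' All rates are percentages. `foldMetrics` holds one row per repeat x fold
#' with the confusion counts and derived metrics; `summary` holds the
#' mean +/- sd of accuracy, sensitivity, specificity, kappa and ROC area.
#'
#' @slot selected Character vector of features used by the SVM.
#' @slot foldMetrics data.frame of per-fold confusion counts and metrics.
#' @slot rocAreas Numeric vector, per-repeat ROC area (pooled decision values).
#' @slot summary data.frame with columns metric, mean, sd.
#' @slot pPerm Label-permutation p value (NA if not run).
#' @slot config List of classifier settings used.
#' @export
setClass("ClassifierReport",
  representation(selected = "character", foldMetrics = "data.frame",
                 rocAreas = "numeric", summary = "data.frame",
                 pPerm = "numeric", config = "list"),
  validity = function(object) {
    rates <- object@foldMetrics[, c("accuracy", "sensitivity", "specificity")]
    if (nrow(object@foldMetrics) && (min(rates) < 0 || max(rates) > 100))
      return("rates must be percentages in [0, 100]")
    TRUE
  }
)

setMethod("show", "ClassifierReport", function(object) {
  cat("ClassifierReport:", length(object@selected), "features,",
      nrow(object@foldMetrics), "test folds\n")
  s <- object@summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %6.2f +/- %5.2f %%\n", s$metric[k], s$mean[k], s$sd[k]))
  }
  if (!is.na(object@pPerm)) cat("  permutation p:", format(object@pPerm, digits = 4), "\n")
})
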