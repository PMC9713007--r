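## LASSO feature selection + linear SVM classification with repeated
## stratified cross-validation, the standard confusion-matrix metrics,
## ROC concordance area, and a label-permutation significance test.

#' Classifier configuration
#'
#' @param C Linear SVM misclassification penalty (default 1, the
#'   conventional default).
#' @param nFolds Cross-validation folds.
#' @param nRepeats Repeats of the k-fold split for the performance estimate.
#' @param lassoRepeats,lassoFolds Repeated-CV scheme for the LASSO penalty.
#' @param lambdaRule `"min"` (deviance-minimizing penalty) or `"one_se"`.
#' @param selectionMode `"nested"` redoes LASSO selection inside every
#'   training fold (no selection leakage); `"paper"` selects once on the
#'   full data before cross-validation, replicating the publication-style
#'   procedure.
#' @param nPerm Label permutations for the significance test.
#' @param seed Integer seed.
#' @param paperConvention If TRUE permutation p = count/nPerm (can be 0);
#'   default +1-corrected.
#' @return List of class `ClassifierConfig`.
#' @export
classifierConfig <- function(C = 1, nFolds = 5L, nRepeats = 100L,
                             lassoRepeats = 10L, lassoFolds = 5L,
                             lambdaRule = c("min", "one_se"),
                             selectionMode = c("nested", "paper"),
                             nPerm = 5000L, seed = 1L,
                             paperConvention = FALSE) {
  cfg <- list(C = C, nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
              lassoRepeats = as.integer(lassoRepeats),
              lassoFolds = as.integer(lassoFolds),
              lambdaRule = match.arg(lambdaRule),
              selectionMode = match.arg(selectionMode),
              nPerm = as.integer(nPerm), seed = as.integer(seed),
              paperConvention = paperConvention)
  stopifnot(cfg$C > 0, cfg$nFolds >= 2, cfg$nRepeats >= 1,
            cfg$lassoRepeats >= 1, cfg$lassoFolds >= 2)
  class(cfg) <- "ClassifierConfig"
  cfg
}

## glmnet cautions whenever a CV class drops below 8 subjects, which is
## routine for desk-scale cohorts; that specific warning is muffled.
.quietGlmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

.featureMatrix <- function(features) {
  if (is(features, "SummarizedExperiment")) t(assay(features, "auc"))
  else as.matrix(features)            # subjects x features
}

.binaryLabels <- function(labels, positiveClass = NULL) {
  f <- factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two classes", call. = FALSE)
  if (is.null(positiveClass)) {
    positiveClass <- if ("patient" %in% levels(f)) "patient" else levels(f)[2]
  }
  f <- stats::relevel(f, ref = setdiff(levels(f), positiveClass))
  attr(f, "positive") <- positiveClass
  f
}

## Stratified fold assignment; every fold gets both classes whenever the
## class sizes allow it. Uses the current RNG stream.
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    ix <- which(labels == cl)
    fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  fold
}

#' LASSO feature selection by repeated cross-validation
#'
#' L1-penalized logistic regression over the glmnet path; the penalty is
#' chosen by the `lambdaRule` applied to the cross-validated binomial
#' deviance averaged over `lassoRepeats` stratified `lassoFolds`-fold
#' splits. Features are standardized internally for the penalty; selection
#' is reported on the original feature names (nonzero coefficients at the
#' chosen penalty).
#'
#' @param features SummarizedExperiment (features x subjects) or a
#'   subjects-by-features matrix.
#' @param labels Two-class label vector aligned with subjects.
#' @param cfg A [classifierConfig()].
#' @param lambda Optional fixed penalty overriding the CV choice.
#' @return Character vector of selected feature names (possibly empty).
#' @export
lassoSelect <- function(features, labels, cfg = classifierConfig(),
                        lambda = NULL) {
  x <- .featureMatrix(features)
  y <- .binaryLabels(labels)
  if (min(table(y)) < 2) stop("need at least two subjects per class", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- .quietGlmnet(glmnet::glmnet(x, y, family = "binomial", standardize = TRUE))
  if (is.null(lambda)) {
    path <- fit$lambda
    cvm <- matrix(NA_real_, length(path), cfg$lassoRepeats)
    cvsd <- matrix(NA_real_, length(path), cfg$lassoRepeats)
    withSeed(childSeed(cfg$seed, "lasso-cv"), {
      for (r in seq_len(cfg$lassoRepeats)) {
        foldid <- .stratifiedFolds(y, cfg$lassoFolds)
        cv <- .quietGlmnet(
          glmnet::cv.glmnet(x, y, family = "binomial", lambda = path,
                            foldid = foldid, standardize = TRUE))
        ix <- match(cv$lambda, path)
        cvm[ix, r] <- cv$cvm
        cvsd[ix, r] <- cv$cvsd
      }
    })
    mcvm <- rowMeans(cvm, na.rm = TRUE)
    kmin <- which.min(mcvm)
    lambda <- if (cfg$lambdaRule == "min") {
      path[kmin]
    } else {
      thr <- mcvm[kmin] + mean(cvsd[kmin, ], na.rm = TRUE)
      path[min(which(mcvm <= thr))]
    }
  }
  cf <- as.matrix(glmnet::coef.glmnet(fit, s = lambda))
  sel <- rownames(cf)[cf[, 1] != 0]
  setdiff(sel, "(Intercept)")
}

#' Min-max scaling learned on the training block
#'
#' Per feature: `(x - min_train) / (max_train - min_train)`. Constant
#' training features map to 0 everywhere; test values may fall outside
#' \[0, 1\] (the training parameters are applied unchanged).
#'
#' @param train Training feature block (subjects x features).
#' @param applyTo Optional block scaled with the training parameters.
#' @return List with `train`, `applyTo` (NULL if absent), `min`, `range`.
#' @export
minmaxScale <- function(train, applyTo = NULL) {
  train <- as.matrix(train)
  lo <- apply(train, 2, min)
  rg <- apply(train, 2, max) - lo
  scaleBlock <- function(b) {
    b <- as.matrix(b)
    out <- sweep(b, 2, lo)
    out <- sweep(out, 2, ifelse(rg > 0, rg, 1), "/")
    out[, rg == 0] <- 0
    out
  }
  list(train = scaleBlock(train),
       applyTo = if (!is.null(applyTo)) scaleBlock(applyTo),
       min = lo, range = rg)
}

#' ROC area as the Mann-Whitney concordance probability
#'
#' Probability that a randomly chosen positive-class score exceeds a
#' randomly chosen negative-class score, ties counting one half.
#'
#' @param scores Decision values (higher = more positive-class).
#' @param labels Two-class labels.
#' @param positiveClass Positive class (default `"patient"` when present,
#'   else the second factor level).
#' @return Scalar in \[0, 1\].
#' @export
rocArea <- function(scores, labels, positiveClass = NULL) {
  if (length(unique(as.character(labels))) < 2)
    stop("both classes required", call. = FALSE)
  y <- .binaryLabels(labels, positiveClass)
  pos <- y == attr(y, "positive")
  if (!any(pos) || all(pos)) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

.confusionMetrics <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  c(accuracy = 100 * po,
    sensitivity = 100 * if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = 100 * if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    kappa = 100 * kappa)
}

## One repeat of stratified k-fold CV. Returns per-fold confusion counts and
## the pooled decision values/labels of the repeat. Selection is redone per
## training fold when selected = NULL (nested mode).
.cvOneRepeat <- function(x, y, cfg, selected = NULL) {
  k <- cfg$nFolds
  for (attempt in 1:20) {
    fold <- .stratifiedFolds(y, k)
    if (all(vapply(seq_len(k), function(f) length(unique(y[fold == f])) == 2,
                   logical(1)))) break
    if (attempt == 20) stop("could not draw folds containing both classes", call. = FALSE)
    message("redrawing a fold split with a single-class fold")
  }
  pos <- attr(y, "positive")
  folds <- vector("list", k)
  dec <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    sel <- selected
    if (is.null(sel)) {
      sel <- lassoSelect(x[!test, , drop = FALSE], y[!test], cfg)
      if (!length(sel)) sel <- colnames(x)  # null selection: fall back to all
    }
    sc <- minmaxScale(x[!test, sel, drop = FALSE], x[test, sel, drop = FALSE])
    model <- e1071::svm(sc$train, y[!test], kernel = "linear", cost = cfg$C,
                        scale = FALSE)
    pr <- predict(model, sc$applyTo, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    ## orient decision values so larger = positive class
    dvName <- colnames(attr(pr, "decision.values"))[1]
    if (!startsWith(dvName, pos)) dv <- -dv
    dec[test] <- dv
    tp <- sum(pr == pos & y[test] == pos)
    fn <- sum(pr != pos & y[test] == pos)
    fp <- sum(pr == pos & y[test] != pos)
    tn <- sum(pr != pos & y[test] != pos)
    folds[[f]] <- c(fold = f, tp = tp, fn = fn, fp = fp, tn = tn,
                    .confusionMetrics(tp, fn, fp, tn))
  }
  list(folds = do.call(rbind, folds), decision = dec)
}

#' Repeated cross-validated linear SVM with LASSO feature selection
#'
#' Repeats stratified k-fold cross-validation `nRepeats` times. In
#' `selectionMode = "paper"` the LASSO selection is done once on the full
#' data before cross-validation (the publication-style order, which leaks
#' the selection step); in `"nested"` it is redone inside every training
#' fold. Min-max scaling is always learned on the training folds only.
#' Accuracy, sensitivity (patient class), specificity, and chance-corrected
#' kappa are aggregated over all repeats x folds; the ROC area is computed
#' per repeat from the pooled decision values and reported mean +/- sd.
#'
#' @inheritParams lassoSelect
#' @param positiveClass Class treated as "patient" for sensitivity.
#' @return A [ClassifierReport-class] (permutation p is NA; see
#'   [permutationTestAccuracy()]).
#' @export
crossValidateSvm <- function(features, labels, cfg = classifierConfig(),
                             positiveClass = NULL) {
  x <- .featureMatrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- .binaryLabels(labels, positiveClass)
  selected <- NULL
  if (cfg$selectionMode == "paper") {
    selected <- lassoSelect(x, y, cfg)
    if (!length(selected)) selected <- colnames(x)
  }
  allFolds <- vector("list", cfg$nRepeats)
  rocs <- numeric(cfg$nRepeats)
  withSeed(childSeed(cfg$seed, "svm-cv"), {
    for (r in seq_len(cfg$nRepeats)) {
      rep <- .cvOneRepeat(x, y, cfg, selected)
      allFolds[[r]] <- cbind(repeat_ = r, rep$folds)
      rocs[r] <- rocArea(rep$decision, y, attr(y, "positive"))
    }
  })
  fm <- as.data.frame(do.call(rbind, allFolds))
  metrics <- c("accuracy", "sensitivity", "specificity", "kappa")
  summ <- data.frame(
    metric = c(metrics, "roc_auc"),
    mean = c(vapply(fm[metrics], mean, numeric(1)), 100 * mean(rocs)),
    sd = c(vapply(fm[metrics], sd, numeric(1)), 100 * sd(rocs)))
  new("ClassifierReport",
      selected = if (is.null(selected)) character(0) else selected,
      foldMetrics = fm, rocAreas = rocs, summary = summ,
      pPerm = NA_real_, config = unclass(cfg))
}

#' Label-permutation test of the cross-validated accuracy
#'
#' Re-runs one round of k-fold cross-validation on randomly relabeled data
#' `nPerm` times and compares the permuted mean accuracies with the real
#' cross-validated mean accuracy (one-tailed). In `selectionMode = "paper"`
#' the permuted runs reuse the feature set already selected on the real
#' labels, matching the publication-style procedure (relabel, then
#' cross-validate the fixed classifier pipeline); in `"nested"` the
#' selection is redone inside every permuted training fold.
#'
#' @inheritParams crossValidateSvm
#' @param report Optional [ClassifierReport-class] already computed on the
#'   real labels (avoids refitting); must match `features`/`cfg`.
#' @return List with `pPerm`, `realAccuracy`, `permAccuracies`.
#' @export
permutationTestAccuracy <- function(features, labels, cfg = classifierConfig(),
                                    positiveClass = NULL, report = NULL) {
  stopifnot(cfg$nPerm >= 1)
  x <- .featureMatrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- .binaryLabels(labels, positiveClass)
  if (is.null(report)) {
    report <- crossValidateSvm(x, y, cfg, attr(y, "positive"))
  }
  realAcc <- report@summary$mean[report@summary$metric == "accuracy"]
  permCfg <- cfg
  permCfg$nRepeats <- 1L
  permAcc <- numeric(cfg$nPerm)
  withSeed(childSeed(cfg$seed, "label-perm"), {
    selected <- NULL
    if (cfg$selectionMode == "paper") {
      selected <- report@selected
      if (!length(selected)) selected <- colnames(x)
    }
    for (b in seq_len(cfg$nPerm)) {
      yb <- y[sample.int(length(y))]
      attr(yb, "positive") <- attr(y, "positive")
      rep <- .cvOneRepeat(x, yb, permCfg, selected)
      permAcc[b] <- mean(rep$folds[, "accuracy"])
    }
  })
  count <- sum(permAcc >= realAcc)
  p <- if (cfg$paperConvention) count / cfg$nPerm else (1 + count) / (cfg$nPerm + 1)
  list(pPerm = p, realAccuracy = realAcc, permAccuracies = permAcc)
}
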