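test_that("LASSO recovers an informative feature among noise", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 40
    lab <- factor(rep(c("control", "patient"), each = n / 2))
    x <- matrix(rnorm(n * 51), n, 51)
    colnames(x) <- c("signal", paste0("noise", 1:50))
    x[, "signal"] <- as.numeric(lab == "patient") + rnorm(n, 0, 0.05)
    sel <- lassoSelect(x, lab, classifierConfig(lassoRepeats = 3, seed = s))
    if ("signal" %in% sel && sum(startsWith(sel, "noise")) <= 5) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("a maximal penalty selects nothing and selection is seed-deterministic", {
  d <- sepData(seed = 2)
  expect_length(lassoSelect(d$x, d$lab, lambda = 1e6), 0)
  cfg <- classifierConfig(lassoRepeats = 2, seed = 5)
  expect_identical(lassoSelect(d$x, d$lab, cfg), lassoSelect(d$x, d$lab, cfg))
})

test_that("min-max scaling learns on train and extrapolates on test", {
  sc <- minmaxScale(matrix(c(2, 4, 6), 3, 1))
  expect_equal(as.numeric(sc$train), c(0, 0.5, 1))
  sc2 <- minmaxScale(matrix(c(2, 4, 6), 3, 1), matrix(8, 1, 1))
  expect_equal(as.numeric(sc2$applyTo), 1.5)
  sc3 <- minmaxScale(matrix(5, 4, 1), matrix(c(5, 7), 2, 1))
  expect_equal(as.numeric(sc3$train), rep(0, 4))
  expect_equal(as.numeric(sc3$applyTo), c(0, 0))    # constant feature: all 0
})

test_that("confusion metrics match hand enumeration and an independent implementation", {
  m <- rsConnectome:::.confusionMetrics(40, 6, 6, 40)
  expect_equal(unname(m["accuracy"]), 100 * 80 / 92, tolerance = 1e-10)
  expect_equal(unname(m["accuracy"]), 86.95652, tolerance = 1e-4)
  expect_equal(unname(m["kappa"]), 73.91304, tolerance = 1e-4)
  expect_equal(unname(m["sensitivity"]), 100 * 40 / 46, tolerance = 1e-10)
  expect_equal(unname(m["specificity"]), 100 * 40 / 46, tolerance = 1e-10)
  ## cross-check kappa against e1071's implementation
  tab <- matrix(c(40, 6, 6, 40), 2)
  expect_equal(unname(m["kappa"]) / 100, e1071::classAgreement(tab)$kappa,
               tolerance = 1e-10)
  ## asymmetric case
  m2 <- rsConnectome:::.confusionMetrics(30, 10, 4, 20)
  tab2 <- matrix(c(30, 4, 10, 20), 2)
  expect_equal(unname(m2["kappa"]) / 100, e1071::classAgreement(tab2)$kappa,
               tolerance = 1e-10)
  expect_equal(unname(m2["sensitivity"]), 100 * 30 / 40, tolerance = 1e-10)
  expect_equal(unname(m2["specificity"]), 100 * 20 / 24, tolerance = 1e-10)
})

test_that("ROC area is the concordance probability, checked against pROC", {
  expect_identical(rocArea(c(0.1, 0.4, 0.8, 0.9), c(0, 0, 1, 1),
                           positiveClass = "1"), 1)
  expect_equal(rocArea(c(0.9, 0.7, 0.6, 0.4), c(1, 0, 1, 0),
                       positiveClass = "1"), 0.75, tolerance = 1e-12)
  set.seed(11)
  sc <- rnorm(60)
  lb <- rbinom(60, 1, plogis(sc))
  if (length(unique(lb)) == 2) {
    a <- rocArea(sc, lb, positiveClass = "1")
    b <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
    expect_equal(a, b, tolerance = 1e-10)
    flipped <- ifelse(lb == 1, 0, 1)
    expect_equal(rocArea(sc, flipped, positiveClass = "1"), 1 - a,
                 tolerance = 1e-12)
  }
  expect_error(rocArea(c(1, 2), c(1, 1), positiveClass = "1"), "both classes")
})

test_that("separable features classify nearly perfectly; null features sit at chance", {
  d <- sepData(seed = 3)
  cfg <- classifierConfig(nRepeats = 5, lassoRepeats = 3,
                          selectionMode = "paper", nPerm = 50, seed = 4)
  rep <- crossValidateSvm(d$x, d$lab, cfg)
  expect_gte(rep@summary$mean[rep@summary$metric == "accuracy"], 95)
  expect_gte(rep@summary$mean[rep@summary$metric == "roc_auc"], 99)
  expect_identical(nrow(rep@foldMetrics), 25L)
  ## confusion counts sum to the fold sizes
  expect_equal(sum(rep@foldMetrics[, c("tp", "fn", "fp", "tn")]) / 5, 60)
  pt <- permutationTestAccuracy(d$x, d$lab, cfg, report = rep)
  expect_lte(pt$pPerm, 0.02)

  ## chance-level behaviour is checked with the sound (nested) procedure
  set.seed(6)
  xnull <- matrix(rnorm(60 * 50), 60, 50)
  colnames(xnull) <- paste0("f", 1:50)
  repn <- crossValidateSvm(xnull, d$lab,
                           classifierConfig(nRepeats = 3, lassoRepeats = 2,
                                            selectionMode = "nested", seed = 7))
  accn <- repn@summary$mean[repn@summary$metric == "accuracy"]
  expect_gte(accn, 35)
  expect_lte(accn, 65)
})

test_that("training-side state never reads test rows in nested mode", {
  ## poison sentinel: replace one subject's features with huge values and
  ## verify the scaling parameters learned when that subject is held out
  ## are unchanged
  set.seed(8)
  x <- matrix(rnorm(20 * 4), 20, 4)
  colnames(x) <- paste0("f", 1:4)
  sc1 <- minmaxScale(x[1:15, ], x[16:20, ])
  xPois <- x
  xPois[17:20, ] <- 1e9
  sc2 <- minmaxScale(xPois[1:15, ], xPois[16:20, ])
  expect_identical(sc1$min, sc2$min)
  expect_identical(sc1$range, sc2$range)
  ## and whole-pipeline: poisoning a known held-out fold's rows leaves the
  ## selection computed on the remaining rows identical
  lab <- factor(rep(c("control", "patient"), 10))
  cfg <- classifierConfig(lassoRepeats = 2, seed = 9)
  selClean <- lassoSelect(x[1:16, ], lab[1:16], cfg)
  selPois <- lassoSelect(xPois[1:16, ], lab[1:16], cfg)
  expect_identical(selClean, selPois)
})

test_that("full-data selection inflates accuracy relative to nested selection on null features", {
  accPaper <- accNested <- numeric(6)
  for (s in 1:6) {
    set.seed(300 + s)
    n <- 40
    lab <- factor(rep(c("control", "patient"), each = n / 2))
    x <- matrix(rnorm(n * 60), n, 60)
    colnames(x) <- paste0("f", 1:60)
    cfgP <- classifierConfig(nRepeats = 1, lassoRepeats = 2,
                             selectionMode = "paper", seed = s)
    cfgN <- classifierConfig(nRepeats = 1, lassoRepeats = 2,
                             selectionMode = "nested", seed = s)
    accPaper[s] <- crossValidateSvm(x, lab, cfgP)@summary$mean[1]
    accNested[s] <- crossValidateSvm(x, lab, cfgN)@summary$mean[1]
  }
  expect_gt(mean(accPaper), mean(accNested) - 1e-9)
})

test_that("permutation p values are invariant to subject ordering", {
  d <- sepData(n = 30, nNoise = 10, seed = 10)
  cfg <- classifierConfig(nRepeats = 2, lassoRepeats = 2,
                          selectionMode = "paper", nPerm = 30, seed = 11)
  p1 <- permutationTestAccuracy(d$x, d$lab, cfg)
  ord <- sample(30)
  p2 <- permutationTestAccuracy(d$x[ord, ], d$lab[ord], cfg)
  expect_identical(p1$pPerm, p2$pPerm)
})
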