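## Shared fixtures: small hand-built graphs, cohort -> connectivity stacks,
## and a memoised cache of heavy null-cohort simulations shared between the
## property tests and the calibration acceptance tests.

labelled <- function(m, prefix = "n") {
  dimnames(m) <- list(paste0(prefix, seq_len(nrow(m))),
                      paste0(prefix, seq_len(nrow(m))))
  m
}

## complete graph on n nodes with unit weights, as a z-style matrix
completeZ <- function(n) {
  m <- matrix(1, n, n)
  diag(m) <- 0
  labelled(m)
}

## path graph 1-2-3 with unit weights
pathZ3 <- function() {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1
  m[2, 3] <- m[3, 2] <- 1
  labelled(m)
}

## star: center node 1 with k leaves
starZ <- function(k) {
  m <- matrix(0, k + 1, k + 1)
  m[1, -1] <- m[-1, 1] <- 1
  labelled(m)
}

## two disjoint unit-weight K4 cliques
twoK4Z <- function() {
  m <- matrix(0, 8, 8)
  m[1:4, 1:4] <- 1
  m[5:8, 5:8] <- 1
  diag(m) <- 0
  labelled(m)
}

unitWeights <- function(g) {
  igraph::E(g)$weight <- 1
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  g
}

## Watts-Strogatz graph N=100, k=10 (nei = 5), rewiring p
wsGraph <- function(p, seed = 1) {
  set.seed(seed)
  unitWeights(igraph::sample_smallworld(1, 100, 5, p))
}

erGraph <- function(pEdge = 0.15, seed = 1) {
  set.seed(seed)
  unitWeights(igraph::sample_gnp(100, pEdge))
}

## ridge connectivity stack of a cohort
cohortStack <- function(cohort, alpha = 0.1) {
  ts <- timeSeries(cohort)
  lapply(names(ts), function(id) connectivityMatrix(ts[[id]], alpha, id))
}

## planted 8-edge component on nodes 1..6 (the recovery scenario)
plantedEdges8 <- function(delta = 0.3) {
  data.frame(i = c(1, 1, 2, 2, 3, 3, 4, 4),
             j = c(2, 3, 3, 4, 4, 5, 5, 6),
             delta = delta)
}

## fabricated long-format metric curves for column-arithmetic checks
fakeCurves <- function(nNodes, subjects, grid = c(0.1, 0.2, 0.3)) {
  rois <- sprintf("ROI%03d", seq_len(nNodes))
  do.call(rbind, lapply(subjects, function(s) {
    g <- expand.grid(attribute = c("Cp", "Lp", "Sp", "E.glob", "E.loc", "Q",
                                   "sigma", "omega"),
                     sparsity = grid, stringsAsFactors = FALSE)
    g$roi <- NA_character_
    n <- expand.grid(attribute = c("E.nodal", "btwn.cent"), roi = rois,
                     sparsity = grid, stringsAsFactors = FALSE)
    out <- rbind(g[, c("attribute", "roi", "sparsity")],
                 n[, c("attribute", "roi", "sparsity")])
    out$subject <- s
    out$value <- seq_len(nrow(out)) / nrow(out)
    out
  }))
}

## Independent oracle: partial correlation of nodes i and j as the Pearson
## correlation of their residuals after regressing both on all other nodes.
residualPartialCor <- function(x) {
  x <- scale(x)
  p <- ncol(x)
  out <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      z <- cbind(1, x[, -c(i, j)])
      ri <- lm.fit(z, x[, i])$residuals
      rj <- lm.fit(z, x[, j])$residuals
      out[i, j] <- out[j, i] <- cor(ri, rj)
    }
  }
  out
}

## linearly separable two-class feature set: 3 informative features shifted
## by `gap` SDs in the patient class amid pure-noise features
sepData <- function(n = 60, nNoise = 50, gap = 3, seed = 1) {
  set.seed(seed)
  lab <- factor(rep(c("control", "patient"), each = n / 2),
                levels = c("control", "patient"))
  x <- matrix(rnorm(n * nNoise), n, nNoise)
  colnames(x) <- paste0("f", seq_len(nNoise))
  x[lab == "patient", 1:3] <- x[lab == "patient", 1:3] + gap
  list(x = x, lab = lab)
}

## desk-scale pipeline configuration used by the determinism checks
tinyRunConfig <- function(out, seed = 17) {
  runConfig(
    seed = seed,
    paths = list(output = out),
    simulate = list(nPerGroup = 6, nNodes = 16, nTimepoints = 100,
                    plantedEdges = data.frame(i = 1:2, j = 3:4, delta = 0.35)),
    metrics = list(gridLo = 0.2, gridHi = 0.3, gridStep = 0.05, nRef = 3,
                   louvainRestarts = 3),
    nbs = list(nPerm = 40),
    stats = list(nPermGlobal = 60, nPermLocal = 60),
    classify = list(nRepeats = 2, nPerm = 10, lassoRepeats = 2,
                    selectionMode = "paper"))
}

## ---- memoised null-cohort simulations --------------------------------
## 200 null cohorts (20 vs 20, 60 nodes, 196 timepoints). For each cohort:
##  - p of the largest NBS component (positive direction, 200 permutations;
##    NA when nothing survives the primary threshold),
##  - family-wise min maxstat p over a 246-edge-feature family (200 perms),
##  - maxstat p of a single edge feature at 99 permutations (continuous
##    statistic, used for the uniformity check).
.simCache <- new.env(parent = emptyenv())

nullCohortSims <- function(nSims = 200L) {
  key <- paste0("null", nSims)
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  res <- vector("list", nSims)
  for (s in seq_len(nSims)) {
    cc <- cohortConfig(nPerGroup = 20L, nNodes = 60L, nTimepoints = 196L,
                       seed = 1000L + s)
    cohort <- simulateCohort(cc)
    stack <- cohortStack(cohort)
    des <- designMatrix(phenotypes(cohort))
    nbs <- nbsTest(stack, des, pPrimary = 0.001, nPerm = 200L,
                   direction = "positive", seed = 5000L + s)
    pNbs <- if (length(nbs@components)) nbs@components[[1]]$pPerm else NA_real_
    zfeat <- t(vapply(stack, function(cm) {
      z <- zValues(cm)
      z[upper.tri(z)][seq_len(246)]
    }, numeric(246)))
    colnames(zfeat) <- paste0("e", seq_len(246))
    fam <- setNames(rep("edges", 246), colnames(zfeat))
    ms <- maxstatPermGLM(t(zfeat), des, family = fam, nPerm = 200L,
                         seed = 7000L + s)
    single <- maxstatPermGLM(t(zfeat[, 1, drop = FALSE]), des,
                             family = setNames("one", "e1"), nPerm = 99L,
                             seed = 9000L + s)
    res[[s]] <- c(pNbs = pNbs, pMaxstatMin = min(ms@pPerm),
                  pSingle = unname(single@pPerm))
  }
  out <- as.data.frame(do.call(rbind, res))
  .simCache[[key]] <- out
  out
}
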