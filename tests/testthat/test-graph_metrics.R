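## Independent brute-force oracle: all-pairs shortest paths by
## Floyd-Warshall on an adjacency matrix of edge lengths.
floydWarshall <- function(len) {
  n <- nrow(len)
  d <- len
  d[d == 0] <- Inf
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

test_that("closed-form identities hold on hand-built graphs", {
  gK4 <- thresholdBySparsity(completeZ(4), 1)
  m <- globalMetrics(gK4, smallWorld = FALSE)
  expect_equal(m$Cp, 1, tolerance = 1e-12)
  expect_equal(m$Lp, 1, tolerance = 1e-12)
  expect_equal(m$E.glob, 1, tolerance = 1e-12)
  expect_equal(m$Sp, 3, tolerance = 1e-12)

  gP3 <- thresholdBySparsity(pathZ3(), 2 / 3)
  expect_equal(globalMetrics(gP3, smallWorld = FALSE)$E.glob, 5 / 6,
               tolerance = 1e-12)
  nm <- nodalMetrics(gP3)
  expect_equal(unname(nm$E.nodal[c("n1", "n2", "n3")]), c(0.75, 1, 0.75),
               tolerance = 1e-12)

  gStar <- thresholdBySparsity(starZ(3), 0.5)
  bs <- nodalMetrics(gStar)$btwn.cent
  expect_equal(unname(bs["n1"]), 3, tolerance = 1e-12)
  expect_equal(unname(bs[c("n2", "n3", "n4")]), c(0, 0, 0), tolerance = 1e-12)

  ## all pairs adjacent: betweenness identically zero
  expect_equal(max(nodalMetrics(gK4)$btwn.cent), 0, tolerance = 1e-12)

  gQ <- thresholdBySparsity(twoK4Z(), 12 / 28)
  expect_equal(globalMetrics(gQ, smallWorld = FALSE)$Q, 0.5, tolerance = 1e-12)
})

test_that("unit-weight metrics agree with a brute-force shortest-path oracle", {
  set.seed(20)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.4)
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    dimnames(adj) <- list(paste0("n", 1:n), paste0("n", 1:n))
    g <- thresholdBySparsity(adj + 0, (sum(adj) / 2 + 0.1) / (n * (n - 1) / 2))
    m <- globalMetrics(g, smallWorld = FALSE)
    d <- floydWarshall(adj)
    off <- d[upper.tri(d)]
    expect_equal(m$Lp, mean(off[is.finite(off)]), tolerance = 1e-10)
    inv <- 1 / d; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
    expect_equal(m$E.glob, sum(inv) / (n * (n - 1)), tolerance = 1e-10)
    ## binary clustering: triangles over connected triples
    k <- rowSums(adj)
    tri <- diag(adj %*% adj %*% adj)
    cb <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
    expect_equal(m$Cp, mean(cb), tolerance = 1e-10)
  }
})

test_that("random references preserve degrees and weights and randomize a ring", {
  base <- wsGraph(0, seed = 31)           # perfect ring lattice N=100, k=10
  igraph::E(base)$weight <- runif(igraph::ecount(base), 0.5, 1.5)
  m0 <- globalMetrics(base, smallWorld = FALSE)
  for (s in 1:10) {
    rr <- randomReference(base, seed = s)
    expect_identical(igraph::degree(rr), igraph::degree(base))
    expect_equal(sort(igraph::E(rr)$weight), sort(igraph::E(base)$weight))
    mr <- globalMetrics(rr, smallWorld = FALSE)
    expect_lt(mr$Lp, m0$Lp)
    expect_lt(mr$Cp, m0$Cp)
  }
})

test_that("latticization preserves degrees, raises clustering, and is stable at the optimum", {
  er <- erGraph(0.1, seed = 32)
  c0 <- globalMetrics(er, smallWorld = FALSE)$Cp
  for (s in 1:10) {
    lt <- latticeReference(er, seed = s)
    expect_identical(igraph::degree(lt), igraph::degree(er))
    expect_equal(sort(igraph::E(lt)$weight), sort(igraph::E(er)$weight))
    expect_gt(globalMetrics(lt, smallWorld = FALSE)$Cp, c0)
  }
  ## a perfect ring lattice cannot get closer to a lattice
  ring <- wsGraph(0, seed = 33)
  ringCost <- function(g) {
    el <- igraph::as_edgelist(g, names = FALSE)
    n <- igraph::vcount(g)
    sum(pmin(abs(el[, 1] - el[, 2]), n - abs(el[, 1] - el[, 2])))
  }
  lt <- latticeReference(ring, seed = 34)
  expect_lte(ringCost(lt), ringCost(ring))
})

test_that("small-worldness sigma and omega behave as expected by regime", {
  sigmas <- vapply(1:10, function(s) {
    globalMetrics(wsGraph(0.1, seed = s), nRef = 20, seed = s)$sigma
  }, numeric(1))
  expect_gte(sum(sigmas > 1), 9)

  omegaWs <- globalMetrics(wsGraph(0.1, seed = 41), nRef = 20, seed = 41)$omega
  omegaRing <- globalMetrics(wsGraph(0, seed = 42), nRef = 20, seed = 42)$omega
  omegaEr <- globalMetrics(erGraph(0.15, seed = 43), nRef = 20, seed = 43)$omega
  expect_lt(omegaRing, 0)
  expect_gt(omegaEr, 0)
  expect_lt(abs(omegaWs), abs(omegaRing))
  expect_lt(abs(omegaWs), abs(omegaEr))
  ## the small-world graph sits inside the conventional band
  expect_lt(abs(omegaWs), 0.5)
})

test_that("topology metrics are invariant to a global rescaling of weights", {
  set.seed(50)
  z <- matrix(0, 20, 20)
  z[upper.tri(z)] <- runif(190, 0.1, 1)
  z <- z + t(z)
  dimnames(z) <- list(paste0("n", 1:20), paste0("n", 1:20))
  g1 <- thresholdBySparsity(z, 0.3)
  g2 <- thresholdBySparsity(z * 7.3, 0.3)
  m1 <- globalMetrics(g1, nRef = 5, seed = 3)
  m2 <- globalMetrics(g2, nRef = 5, seed = 3)
  for (k in c("Cp", "Lp", "E.glob", "E.loc", "Q", "sigma", "omega")) {
    expect_equal(m1[[k]], m2[[k]], tolerance = 1e-10, label = k)
  }
  expect_equal(m2$Sp, 7.3 * m1$Sp, tolerance = 1e-10)
})

test_that("metric computation fails on edgeless graphs and zero references", {
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  expect_error(globalMetrics(empty), "no edges")
  expect_error(nodalMetrics(empty), "no edges")
  g <- thresholdBySparsity(completeZ(4), 1)
  expect_error(globalMetrics(g, nRef = 0, smallWorld = TRUE), "reference")
})

test_that("trapezoidal AUC matches closed forms and validates input", {
  grid <- sparsityGrid(0.05, 0.40, 0.01)
  expect_equal(aucOverThresholds(rep(1, 36), grid), 0.35, tolerance = 1e-12)
  expect_equal(aucOverThresholds(grid, grid), (0.40^2 - 0.05^2) / 2,
               tolerance = 1e-12)
  expect_equal(aucOverThresholds(c(2, 4), c(0.1, 0.2)), 0.3, tolerance = 1e-12)
  expect_error(aucOverThresholds(1:3, c(0.1, 0.2)), "length")
  expect_error(aucOverThresholds(1, 0.1), "two grid points")
})

test_that("the AUC feature table has the canonical column arithmetic", {
  se60 <- assembleAucFeatures(fakeCurves(60, c("s1", "s2")))
  expect_identical(nrow(se60), 7L + 2L * 60L)        # 127
  se246 <- assembleAucFeatures(fakeCurves(246, "s1"))
  expect_identical(nrow(se246), 499L)
  se246e <- assembleAucFeatures(fakeCurves(246, "s1"), includeELoc = TRUE)
  expect_identical(nrow(se246e), 500L)
  expect_true(all(c("Cp", "omega", "E.nodal|ROI001", "btwn.cent|ROI246") %in%
                    rownames(se246)))
  expect_false(anyNA(SummarizedExperiment::assay(se246, "auc")))
})

test_that("a missing curve fails naming the subject and attribute", {
  cur <- fakeCurves(4, c("s1", "s2"))
  cur <- cur[!(cur$subject == "s2" & cur$attribute == "Lp"), ]
  expect_error(assembleAucFeatures(cur), "s2.*Lp")
})

test_that("real metric curves integrate into a complete feature table", {
  cc <- cohortConfig(nPerGroup = 2, nNodes = 12, nTimepoints = 80, seed = 60)
  co <- simulateCohort(cc)
  stack <- cohortStack(co)
  ## grid starts at 0.2: sparser 12-node graphs are triangle-free, where
  ## sigma/omega are undefined (0/0 clustering ratios)
  grid <- sparsityGrid(0.2, 0.3, 0.05)
  curves <- do.call(rbind, lapply(stack, function(cm) {
    metricCurves(cm, grid, nRef = 3, seed = 1, louvainRestarts = 3)
  }))
  se <- assembleAucFeatures(curves, phenotypes(co))
  expect_identical(dim(se), c(7L + 24L, 4L))
  expect_false(anyNA(SummarizedExperiment::assay(se)))
  expect_identical(colnames(se), phenotypes(co)$subject_id)
})
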