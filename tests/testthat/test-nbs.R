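## tiny deterministic stack: nSub subjects, nNodes nodes, optional shift on
## one edge in the patient half
makeStack <- function(nSub, nNodes, shiftEdge = NULL, shift = 0, noise = 1,
                      seed = 1) {
  set.seed(seed)
  lapply(seq_len(nSub), function(s) {
    z <- matrix(0, nNodes, nNodes)
    z[upper.tri(z)] <- rnorm(nNodes * (nNodes - 1) / 2, sd = noise)
    z <- z + t(z)
    if (!is.null(shiftEdge) && s > nSub / 2) {
      z[shiftEdge[1], shiftEdge[2]] <- z[shiftEdge[1], shiftEdge[2]] + shift
      z[shiftEdge[2], shiftEdge[1]] <- z[shiftEdge[1], shiftEdge[2]]
    }
    dimnames(z) <- list(paste0("n", 1:nNodes), paste0("n", 1:nNodes))
    fisherZ(tanh(z), alpha = 0.1, subjectID = sprintf("s%02d", s))
  })
}

twoGroupPheno <- function(nSub) {
  data.frame(subject_id = sprintf("s%02d", seq_len(nSub)),
             group = factor(rep(c("control", "patient"), each = nSub / 2),
                            levels = c("control", "patient")))
}

test_that("the edge-wise GLM reproduces the pooled two-sample t statistic", {
  stack <- makeStack(16, 8, seed = 2)
  des <- designMatrix(twoGroupPheno(16))
  tm <- edgewiseGLM(stack, des)
  expect_identical(attr(tm, "df"), 14L)
  ## direct pooled-variance two-sample t on every edge
  z <- sapply(stack, function(cm) zValues(cm)[upper.tri(zValues(cm))])
  g2 <- 9:16
  tDirect <- apply(z, 1, function(v) {
    unname(t.test(v[g2], v[-g2], var.equal = TRUE)$statistic)
  })
  expect_equal(tm[upper.tri(tm)], tDirect, tolerance = 1e-10)
  expect_true(isSymmetric(tm))
  expect_equal(unname(diag(tm)), rep(0, 8))
})

test_that("zero-variance edges are flagged degenerate with t = 0", {
  stack <- makeStack(10, 5, seed = 3)
  ## make edge (1,2) exactly constant within groups but shifted between them
  stack <- lapply(seq_along(stack), function(s) {
    z <- zValues(stack[[s]])
    z[1, 2] <- z[2, 1] <- if (s > 5) 1 else 0
    fisherZ(tanh(z), alpha = 0.1, subjectID = subjectID(stack[[s]]))
  })
  des <- designMatrix(twoGroupPheno(10))
  tm <- edgewiseGLM(stack, des)
  expect_identical(tm[1, 2], 0)
  expect_true(length(attr(tm, "degenerateEdges")) >= 1)
})

test_that("reordering subjects together with design rows leaves the t matrix unchanged", {
  stack <- makeStack(12, 6, seed = 4)
  ph <- twoGroupPheno(12)
  ph$age <- rnorm(12, 35, 5)
  des <- designMatrix(ph, "age")
  tm <- edgewiseGLM(stack, des)
  perm <- sample(12)
  des2 <- designMatrix(ph[perm, ], "age")
  tm2 <- edgewiseGLM(stack[perm], des2)
  expect_equal(tm, tm2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("component extraction matches hand-built cases", {
  n <- 12
  tm <- matrix(0, n, n, dimnames = list(paste0("n", 1:n), paste0("n", 1:n)))
  ## a 4-edge path 1-2-3-4-5 and a disjoint 2-edge path 7-8-9
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 5))) {
    tm[e[1], e[2]] <- tm[e[2], e[1]] <- 5
  }
  for (e in list(c(7, 8), c(8, 9))) {
    tm[e[1], e[2]] <- tm[e[2], e[1]] <- 4
  }
  comps <- suprathresholdComponents(tm, 3)
  expect_length(comps, 2)
  expect_equal(unname(vapply(comps, function(co) co$nEdges, numeric(1))), c(4, 2))
  expect_identical(comps[[1]]$nodes, paste0("n", 1:5))

  ## threshold above the global max: nothing survives
  expect_length(suprathresholdComponents(tm, 10), 0)

  ## fully suprathreshold K5
  k5 <- matrix(8, 5, 5); diag(k5) <- 0
  dimnames(k5) <- list(paste0("n", 1:5), paste0("n", 1:5))
  c5 <- suprathresholdComponents(k5, 1)
  expect_length(c5, 1)
  expect_equal(c5[[1]]$nEdges, 10)
  expect_length(c5[[1]]$nodes, 5)
})

test_that("nbs detects a strongly shifted edge and respects direction symmetry", {
  stack <- makeStack(20, 10, shiftEdge = c(2, 7), shift = 3, noise = 0.4,
                     seed = 5)
  ph <- twoGroupPheno(20)
  des <- designMatrix(ph)
  res <- nbsTest(stack, des, pPrimary = 0.001, nPerm = 99, seed = 6)
  expect_s4_class(res, "NBSResult")
  expect_gte(length(res@components), 1)
  expect_true(any(apply(res@components[[1]]$edges, 1, function(e)
    setequal(e, c("n2", "n7")))))
  expect_lt(res@components[[1]]$pPerm, 0.05)
  ## observed max component size equals the first component's size
  expect_equal(res@components[[1]]$nEdges,
               max(vapply(res@components, function(co) co$nEdges, numeric(1))))

  ## swapping group labels and flipping direction reproduces the components
  ph2 <- ph
  ph2$group <- factor(ifelse(ph$group == "patient", "control", "patient"),
                      levels = c("control", "patient"))
  res2 <- nbsTest(stack, designMatrix(ph2), pPrimary = 0.001, nPerm = 99,
                  direction = "negative", seed = 6)
  expect_identical(lapply(res@components, `[[`, "edges"),
                   lapply(res2@components, `[[`, "edges"))
})

test_that("permutation p values are invariant to subject ordering and stable across seeds", {
  stack <- makeStack(10, 6, shiftEdge = c(1, 4), shift = 2.5, noise = 0.5,
                     seed = 7)
  ph <- twoGroupPheno(10)
  res <- nbsTest(stack, designMatrix(ph), pPrimary = 0.01, nPerm = 400, seed = 8)
  perm <- c(3, 9, 1, 6, 10, 2, 8, 4, 7, 5)
  resP <- nbsTest(stack[perm], designMatrix(ph[perm, ]), pPrimary = 0.01,
                  nPerm = 400, seed = 8)
  expect_identical(res@components[[1]]$nEdges, resP@components[[1]]$nEdges)
  ## permutation distributions are exchangeable-identical across orderings
  expect_lt(abs(res@components[[1]]$pPerm - resP@components[[1]]$pPerm), 0.05)

  ## Monte-Carlo stability: p varies across seeds within ~2 SE
  ps <- vapply(1:5, function(s) {
    nbsTest(stack, designMatrix(ph), pPrimary = 0.01, nPerm = 400,
            seed = 100 + s)@components[[1]]$pPerm
  }, numeric(1))
  se <- sqrt(mean(ps) * (1 - mean(ps)) / 400)
  expect_lt(max(ps) - min(ps), 4 * se + 1e-9)
})

test_that("design validation rejects rank deficiency and undersized cohorts", {
  ph <- twoGroupPheno(8)
  ph$dup <- as.numeric(ph$group == "patient")
  expect_error(designMatrix(ph, "dup"), "rank deficient")
  stack <- makeStack(4, 5, seed = 9)
  ph4 <- twoGroupPheno(4)
  ph4$a <- rnorm(4); ph4$b <- rnorm(4)
  expect_error(edgewiseGLM(stack, designMatrix(ph4, c("a", "b"))),
               "fewer subjects")
})
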