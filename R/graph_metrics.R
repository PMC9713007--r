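## Weighted graph topology: global and nodal attributes at one sparsity,
## degree-preserving random/lattice reference nulls for small-worldness,
## and AUC integration of metric curves over the sparsity grid.
##
## Conventions (documented in the methods vignette):
##  - weights are rescaled to max 1 before any metric, so topology is
##    invariant to a global rescaling of the connectivity values;
##  - edge length for shortest paths is 1/weight (stronger = closer);
##  - disconnected graphs: Lp averages finite distances only, efficiencies
##    count unreachable pairs as 0;
##  - clustering is Onnela's geometric-mean form.

.weightedAdjacency <- function(g, normalize = TRUE) {
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  if (any(w <= 0)) stop("graph weights must be strictly positive", call. = FALSE)
  a <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  if (normalize && max(a) > 0) a <- a / max(a)
  a
}

.onnelaClusteringVector <- function(a) {
  k <- rowSums(a > 0)
  w3 <- a^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  c3 <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  c3
}

.distancesInvWeight <- function(g) {
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  w <- w / max(w)
  igraph::distances(g, weights = 1 / w)
}

.efficiencyFromDistances <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  n <- nrow(d)
  if (n < 2) return(0)
  sum(inv) / (n * (n - 1))
}

#' Global weighted topological attributes at one sparsity
#'
#' Computes the clustering coefficient (Cp, Onnela form), characteristic
#' path length (Lp, mean of finite pairwise 1/weight distances), network
#' strength (Sp, mean nodal strength on the raw weights), local and global
#' efficiency, Louvain modularity (best of `louvainRestarts` randomized
#' restarts) and, when `smallWorld = TRUE`, small-worldness sigma and omega
#' against `nRef` degree-preserving random and lattice reference networks:
#' `sigma = (Cp/<Cp_rand>) / (Lp/<Lp_rand>)` and
#' `omega = <Lp_rand>/Lp - Cp/<Cp_latt>`.
#'
#' @param g Weighted undirected igraph with positive weights and >= 1 edge.
#' @param nRef Number of reference networks for sigma/omega.
#' @param seed Integer seed (references and Louvain restarts).
#' @param louvainRestarts Number of randomized Louvain restarts.
#' @param smallWorld Compute sigma and omega? Requires `nRef >= 1`.
#' @return Named list: Cp, Lp, Sp, E.loc, E.glob, Q, sigma, omega (the last
#'   two `NA` when `smallWorld = FALSE`, and `NaN` on triangle-free graphs
#'   where the clustering ratios are 0/0 — choose grids sparse graphs can
#'   support).
#' @export
globalMetrics <- function(g, nRef = 20L, seed = 1L, louvainRestarts = 10L,
                          smallWorld = TRUE) {
  if (igraph::ecount(g) < 1) stop("graph has no edges", call. = FALSE)
  a <- .weightedAdjacency(g)
  cVec <- .onnelaClusteringVector(a)
  Cp <- mean(cVec)
  d <- .distancesInvWeight(g)
  off <- d[upper.tri(d)]
  Lp <- mean(off[is.finite(off)])
  Eglob <- .efficiencyFromDistances(d)
  Sp <- mean(igraph::strength(g))
  Eloc <- .localEfficiency(g, a)
  Q <- .bestLouvain(g, louvainRestarts, childSeed(seed, "louvain"))
  sigma <- omega <- NA_real_
  if (smallWorld) {
    if (nRef < 1) stop("sigma/omega require at least one reference network", call. = FALSE)
    cpR <- lpR <- cpL <- numeric(nRef)
    for (r in seq_len(nRef)) {
      gr <- randomReference(g, seed = childSeed(seed, "rand-ref", r))
      ar <- .weightedAdjacency(gr)
      cpR[r] <- mean(.onnelaClusteringVector(ar))
      dr <- .distancesInvWeight(gr)
      offr <- dr[upper.tri(dr)]
      lpR[r] <- mean(offr[is.finite(offr)])
      gl <- latticeReference(g, seed = childSeed(seed, "latt-ref", r))
      al <- .weightedAdjacency(gl)
      cpL[r] <- mean(.onnelaClusteringVector(al))
    }
    sigma <- (Cp / mean(cpR)) / (Lp / mean(lpR))
    omega <- mean(lpR) / Lp - Cp / mean(cpL)
  }
  list(Cp = Cp, Lp = Lp, Sp = Sp, E.loc = Eloc, E.glob = Eglob, Q = Q,
       sigma = sigma, omega = omega)
}

.localEfficiency <- function(g, a) {
  n <- igraph::vcount(g)
  eff <- numeric(n)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  for (i in seq_len(n)) {
    nb <- as.integer(adj[[i]])
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(g, nb)
    if (igraph::ecount(sub) == 0) next
    ## neighbor subgraph distances with the parent graph's normalization
    wsub <- igraph::E(sub)$weight / max(igraph::E(g)$weight)
    dsub <- igraph::distances(sub, weights = 1 / wsub)
    eff[i] <- .efficiencyFromDistances(dsub)
  }
  mean(eff)
}

.bestLouvain <- function(g, restarts, seed) {
  withSeed(seed, {
    best <- -Inf
    n <- igraph::vcount(g)
    for (r in seq_len(max(1L, restarts))) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, weights = igraph::E(gp)$weight)
      q <- max(cl$modularity)
      if (q > best) best <- q
    }
    best
  })
}

#' Nodal weighted topological attributes
#'
#' Nodal efficiency `E.nodal(i)` is the mean over other nodes of the inverse
#' 1/weight shortest-path distance (0 for unreachable pairs); betweenness
#' centrality is the standard (unnormalized) shortest-path betweenness on
#' 1/weight edge lengths, with fractional counting of tied geodesics.
#'
#' @inheritParams globalMetrics
#' @return List with numeric vectors `E.nodal` and `btwn.cent`, named by
#'   node label.
#' @export
nodalMetrics <- function(g) {
  if (igraph::ecount(g) < 1) stop("graph has no edges", call. = FALSE)
  d <- .distancesInvWeight(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  enodal <- rowSums(inv) / (nrow(d) - 1)
  w <- igraph::E(g)$weight
  w <- w / max(w)
  btw <- igraph::betweenness(g, weights = 1 / w, directed = FALSE,
                             normalized = FALSE)
  list(E.nodal = setNames(enodal, igraph::V(g)$name),
       btwn.cent = setNames(as.numeric(btw), igraph::V(g)$name))
}

#' Degree-preserving random reference network
#'
#' Maslov-Sneppen double-edge swaps (`nSwapsPerEdge x |E|` attempted swaps)
#' preserve every node's degree exactly; the weight multiset is then
#' reassigned to the rewired edges by a random permutation.
#'
#' @param g Weighted undirected igraph.
#' @param nSwapsPerEdge Attempted swaps per edge.
#' @param seed Integer seed.
#' @return Rewired igraph with the same node set, degree sequence and
#'   weight multiset.
#' @export
randomReference <- function(g, nSwapsPerEdge = 10L, seed = 1L) {
  if (igraph::ecount(g) < 2) stop("need at least two edges to rewire", call. = FALSE)
  withSeed(seed, {
    g2 <- igraph::rewire(g, igraph::keeping_degseq(
      niter = nSwapsPerEdge * igraph::ecount(g)))
    igraph::E(g2)$weight <- sample(igraph::E(g)$weight)
    g2
  })
}

#' Degree-preserving lattice reference network
#'
#' Latticization: double-edge swaps are proposed at random but accepted only
#' when they strictly reduce the total ring distance
#' `sum(min(|i - j|, N - |i - j|))` of the edge set (nodes indexed along a
#' ring in their storage order), driving the topology toward a ring lattice
#' while preserving the degree sequence. The weight multiset is reassigned
#' by random permutation.
#'
#' @param g Weighted undirected igraph.
#' @param nPasses Passes over the edge list.
#' @param seed Integer seed.
#' @return Latticized igraph with identical degree sequence and weight
#'   multiset.
#' @export
latticeReference <- function(g, nPasses = 5L, seed = 1L) {
  m <- igraph::ecount(g)
  if (m < 2) stop("need at least two edges to latticize", call. = FALSE)
  n <- igraph::vcount(g)
  ringDist <- function(i, j) pmin(abs(i - j), n - abs(i - j))
  withSeed(seed, {
    el <- igraph::as_edgelist(g, names = FALSE)
    adj <- matrix(FALSE, n, n)
    adj[el] <- TRUE
    adj[el[, c(2, 1)]] <- TRUE
    for (pass in seq_len(nPasses)) {
      for (e1 in sample.int(m)) {
        e2 <- sample.int(m, 1L)
        if (e2 == e1) next
        a <- el[e1, 1]; b <- el[e1, 2]
        cc <- el[e2, 1]; dd <- el[e2, 2]
        if (length(unique(c(a, b, cc, dd))) < 4) next
        cur <- ringDist(a, b) + ringDist(cc, dd)
        ## two rewiring options: (a-c, b-d) or (a-d, b-c)
        cost1 <- ringDist(a, cc) + ringDist(b, dd)
        cost2 <- ringDist(a, dd) + ringDist(b, cc)
        pick <- if (cost1 <= cost2) 1L else 2L
        newCost <- min(cost1, cost2)
        if (newCost >= cur) next
        if (pick == 1L) { p1 <- c(a, cc); p2 <- c(b, dd) } else { p1 <- c(a, dd); p2 <- c(b, cc) }
        if (adj[p1[1], p1[2]] || adj[p2[1], p2[2]]) next
        adj[a, b] <- adj[b, a] <- FALSE
        adj[cc, dd] <- adj[dd, cc] <- FALSE
        adj[p1[1], p1[2]] <- adj[p1[2], p1[1]] <- TRUE
        adj[p2[1], p2[2]] <- adj[p2[2], p2[1]] <- TRUE
        el[e1, ] <- p1
        el[e2, ] <- p2
      }
    }
    g2 <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g2) < n) g2 <- igraph::add_vertices(g2, n - igraph::vcount(g2))
    igraph::V(g2)$name <- igraph::V(g)$name
    igraph::E(g2)$weight <- sample(igraph::E(g)$weight)
    g2
  })
}

#' Trapezoidal area under a metric curve over the sparsity grid
#'
#' @param values Metric values aligned to `grid`.
#' @param grid Strictly increasing sparsity values (>= 2 points).
#' @return Scalar trapezoidal integral.
#' @export
aucOverThresholds <- function(values, grid) {
  if (length(values) != length(grid)) stop("curve and grid lengths differ", call. = FALSE)
  if (length(grid) < 2) stop("need at least two grid points", call. = FALSE)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  sum(diff(grid) * (head(values, -1) + values[-1]) / 2)
}

#' Metric curves of one subject across the sparsity grid
#'
#' Thresholds the connectivity matrix at every grid sparsity and computes
#' all global and nodal attributes, returning a long-format data.frame
#' (subject, attribute, roi, sparsity, value; `roi` is NA for global
#' attributes).
#'
#' @param cm A [ConnectivityMatrix-class].
#' @param grid Sparsity grid from [sparsityGrid()].
#' @param nRef Reference networks per grid point for sigma/omega.
#' @param seed Integer seed.
#' @param louvainRestarts Louvain restarts per grid point.
#' @param smallWorld Compute sigma/omega curves?
#' @return Long-format data.frame of metric curves.
#' @export
metricCurves <- function(cm, grid, nRef = 20L, seed = 1L,
                         louvainRestarts = 10L, smallWorld = TRUE) {
  out <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    g <- thresholdBySparsity(cm, grid[k])
    gm <- globalMetrics(g, nRef = nRef, seed = childSeed(seed, "metrics", k),
                        louvainRestarts = louvainRestarts,
                        smallWorld = smallWorld)
    nm <- nodalMetrics(g)
    gl <- data.frame(subject = subjectID(cm),
                     attribute = names(gm), roi = NA_character_,
                     sparsity = grid[k],
                     value = unlist(gm, use.names = FALSE))
    nd <- data.frame(subject = subjectID(cm),
                     attribute = rep(c("E.nodal", "btwn.cent"),
                                     each = length(nm$E.nodal)),
                     roi = rep(names(nm$E.nodal), 2),
                     sparsity = grid[k],
                     value = c(nm$E.nodal, nm$btwn.cent))
    out[[k]] <- rbind(gl, nd)
  }
  res <- do.call(rbind, out)
  if (!smallWorld) res <- res[!(res$attribute %in% c("sigma", "omega")), ]
  rownames(res) <- NULL
  res
}

.globalAttributeOrder <- function(includeELoc) {
  base <- c("Cp", "Lp", "Sp", "E.glob", "Q", "sigma", "omega")
  if (includeELoc) append(base, "E.loc", after = 4) else base
}

#' Assemble the subjects-by-features AUC table
#'
#' Integrates every metric curve over the common sparsity grid and arranges
#' the AUC values as a features-by-subjects SummarizedExperiment: one row
#' per global attribute and one per nodal attribute x ROI. With the local
#' efficiency excluded (the default) an N-node cohort yields
#' `7 + 2 N` features.
#'
#' @param curves Long-format curves of all subjects (rbind of
#'   [metricCurves()] outputs).
#' @param phenotypes Optional data.frame with a `subject_id` column,
#'   attached as colData.
#' @param includeELoc Keep the local-efficiency AUC as a feature?
#' @return SummarizedExperiment with assay `auc` (features x subjects),
#'   rowData columns `attribute` and `roi`.
#' @export
assembleAucFeatures <- function(curves, phenotypes = NULL, includeELoc = FALSE) {
  stopifnot(all(c("subject", "attribute", "roi", "sparsity", "value") %in%
                  names(curves)))
  subjects <- unique(curves$subject)
  grid <- sort(unique(curves$sparsity))
  rois <- sort(unique(curves$roi[!is.na(curves$roi)]))
  globalAttrs <- .globalAttributeOrder(includeELoc)
  featAttr <- c(globalAttrs, rep(c("E.nodal", "btwn.cent"), each = length(rois)))
  featRoi <- c(rep(NA_character_, length(globalAttrs)), rois, rois)
  featName <- ifelse(is.na(featRoi), featAttr, paste(featAttr, featRoi, sep = "|"))
  key <- paste(curves$attribute, ifelse(is.na(curves$roi), "", curves$roi))
  mat <- matrix(NA_real_, length(featName), length(subjects),
                dimnames = list(featName, subjects))
  for (s in subjects) {
    rows <- curves$subject == s
    cs <- curves[rows, ]
    ck <- key[rows]
    for (f in seq_along(featName)) {
      fkey <- paste(featAttr[f], ifelse(is.na(featRoi[f]), "", featRoi[f]))
      sel <- ck == fkey
      if (sum(sel) != length(grid)) {
        stop(sprintf("subject %s: missing or incomplete curve for %s", s,
                     featName[f]), call. = FALSE)
      }
      ord <- order(cs$sparsity[sel])
      mat[f, s] <- aucOverThresholds(cs$value[sel][ord], grid)
    }
  }
  cd <- if (!is.null(phenotypes)) {
    idx <- match(subjects, phenotypes$subject_id)
    if (anyNA(idx)) stop("phenotypes missing some subjects", call. = FALSE)
    DataFrame(phenotypes[idx, , drop = FALSE], row.names = subjects)
  } else {
    DataFrame(row.names = subjects)
  }
  se <- SummarizedExperiment(
    assays = list(auc = mat),
    rowData = DataFrame(attribute = featAttr, roi = featRoi,
                        row.names = featName),
    colData = cd)
  metadata(se)$grid <- grid
  metadata(se)$includeELoc <- includeELoc
  se
}
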