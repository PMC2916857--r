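## The extended minimum spanning tree growth algorithm: greedy Prim-like
## attachment of carrier points under the cost
##     cost(p, v) = ||p - v|| + bf * (PL(v) + ||p - v||),
## i.e. Euclidean wiring cost plus bf times the resulting path length from
## the root to the new point.  At bf = 0 the rule is exactly Prim's and the
## result is the Euclidean minimum spanning tree; at large bf trees approach
## direct connections from the root to every point.

# Shared greedy engine.  init* describe the starting tree(s) (one root per
# tree; parent NA at roots).  pointId maps init nodes into the id space of
# the optional extraCost matrix (roots first, then carriers, by convention);
# 0 means "no id".  Returns flat arrays plus the carrier attachment order.
greedyEngine <- function(initPos, initParent, initDiam, initRegion, initTree,
                         pointIdInit, carriers, params, extraCost = NULL,
                         regionLabel = 3L, allowPartial = FALSE) {
  m <- nrow(carriers)
  n0 <- nrow(initPos)
  ntot <- n0 + m
  pos <- rbind(initPos, matrix(0, m, 3))
  parent <- c(initParent, rep(NA_integer_, m))
  diam <- c(initDiam, rep(1, m))
  region <- c(initRegion, rep(as.integer(regionLabel), m))
  treeId <- c(initTree, rep(NA_integer_, m))
  pointId <- c(pointIdInit, rep(0L, m))
  carrierOf <- c(rep(NA_integer_, n0), rep(NA_integer_, m))
  isRoot <- c(is.na(initParent), rep(FALSE, m))

  bf <- params@bf
  cutoff <- params@cutoff
  w <- params@extraCostWeight
  capReg <- params@maxChildren
  capRoot <- params@maxChildrenRoot

  # path length from each tree's own root (init nodes come parents-first)
  pl <- numeric(ntot)
  if (n0 > 1L) {
    for (i in seq_len(n0)) {
      p <- initParent[i]
      if (!is.na(p)) pl[i] <- pl[p] + vnorm(initPos[i, ] - initPos[p, ])
    }
  }
  nchild <- integer(ntot)
  if (n0 > 1L) {
    tb <- tabulate(initParent[!is.na(initParent)], nbins = n0)
    nchild[seq_len(n0)] <- tb
  }
  capOf <- ifelse(isRoot, capRoot, capReg)
  admissible <- nchild < capOf

  if (m == 0L)
    return(list(pos = pos, parent = parent, diam = diam, region = region,
                treeId = treeId, carrierOf = carrierOf, n = n0,
                unconnected = integer(0)))

  carrierIds <- n0 + seq_len(m)   # extraCost ids of the carriers follow init roots

  pairCost <- function(e, plv, vIdx, cIdx) {
    cst <- e * (1 + bf) + bf * plv
    cst[e > cutoff] <- Inf
    if (!is.null(extraCost)) {
      ec <- extraCost[cbind(pointId[vIdx], carrierIds[cIdx])]
      cst <- cst + w * ec
    }
    cst
  }

  bestCost <- rep(Inf, m)
  bestNode <- rep(NA_integer_, m)
  active <- rep(TRUE, m)

  # best attachment for carriers in `js` against all admissible nodes
  rescan <- function(js, nNodes) {
    adm <- which(admissible[seq_len(nNodes)])
    if (!length(adm)) { bestCost[js] <<- Inf; bestNode[js] <<- NA_integer_; return(invisible()) }
    for (j in js) {
      e <- rowDist(pos[adm, , drop = FALSE], carriers[j, ])
      cst <- pairCost(e, pl[adm], adm, rep(j, length(adm)))
      k <- which.min(cst)
      bestCost[j] <<- cst[k]
      bestNode[j] <<- adm[k]
    }
    invisible()
  }
  rescan(seq_len(m), n0)

  nNodes <- n0
  for (step in seq_len(m)) {
    j <- which.min(ifelse(active, bestCost, Inf))
    if (!is.finite(bestCost[j]) || !active[j]) {
      if (allowPartial) break
      stop("carrier point unreachable under the given cutoff/cost graph")
    }
    v <- bestNode[j]
    nNodes <- nNodes + 1L
    e <- vnorm(carriers[j, ] - pos[v, ])
    pos[nNodes, ] <- carriers[j, ]
    parent[nNodes] <- v
    pl[nNodes] <- pl[v] + e
    treeId[nNodes] <- treeId[v]
    pointId[nNodes] <- carrierIds[j]
    carrierOf[nNodes] <- j
    diam[nNodes] <- 1
    region[nNodes] <- regionLabel
    nchild[v] <- nchild[v] + 1L
    admissible[nNodes] <- nchild[nNodes] < capReg
    active[j] <- FALSE

    if (nchild[v] >= capOf[v]) {
      admissible[v] <- FALSE
      orphans <- which(active & bestNode == v)
      if (length(orphans)) rescan(orphans, nNodes)
    }
    act <- which(active)
    if (length(act)) {
      e2 <- rowDist(carriers[act, , drop = FALSE], pos[nNodes, ])
      cst <- pairCost(e2, rep(pl[nNodes], length(act)),
                      rep(nNodes, length(act)), act)
      upd <- cst < bestCost[act]
      if (any(upd)) {
        bestCost[act[upd]] <- cst[upd]
        bestNode[act[upd]] <- nNodes
      }
    }
  }

  keep <- seq_len(nNodes)
  list(pos = pos[keep, , drop = FALSE], parent = parent[keep],
       diam = diam[keep], region = region[keep], treeId = treeId[keep],
       carrierOf = carrierOf[keep], n = nNodes, unconnected = which(active))
}

asCarrierMatrix <- function(carriers) {
  if (is(carriers, "CarrierPointSet")) return(carrierPoints(carriers))
  m <- as.matrix(carriers)
  if (length(m) == 0L) return(matrix(numeric(0), 0, 3))
  if (ncol(m) == 2L) m <- cbind(m, 0)
  m
}

#' Grow a tree over carrier points (extended minimum spanning tree)
#'
#' Starting from a root and an empty tree, repeatedly connects the
#' unconnected carrier point that is cheapest to reach — Euclidean wiring
#' cost plus \code{bf} times the path length from the root to the new point —
#' to the admissible tree node realizing that cost.  With multifurcation
#' suppression (default), non-root nodes accept at most two children.  The
#' procedure is deterministic: cost ties are resolved toward the smallest
#' carrier index, then the smallest node label.
#'
#' @param root numeric length 2 or 3: root position (\eqn{\mu m}).
#' @param carriers a \code{CarrierPointSet} or coordinate matrix.
#' @param params a \code{\link{growthParameters}} object.
#' @param extraCost optional pairwise cost matrix over point ids (root = 1,
#'   carrier j = 1 + j); \code{Inf} forbids a connection.  Used for
#'   image-guided reconstruction.
#' @param allowPartial if TRUE, carriers unreachable under \code{extraCost}
#'   or the cutoff are silently left out (attribute \code{unconnected});
#'   default FALSE errors instead.
#' @param regionLabel region code for grown nodes (default 3); the root gets
#'   region 1 (soma).
#' @return a \code{NeuronTree}; node order is the attachment order, with
#'   attribute \code{carrierIndex} giving, for each node after the root, the
#'   index of the input carrier it came from.
#' @export
growTree <- function(root, carriers, params = growthParameters(),
                     extraCost = NULL, allowPartial = FALSE,
                     regionLabel = 3L) {
  root <- c(as.numeric(root), 0)[1:3]
  cm <- asCarrierMatrix(carriers)
  res <- greedyEngine(initPos = matrix(root, 1, 3),
                      initParent = NA_integer_, initDiam = 1,
                      initRegion = 1L, initTree = 1L, pointIdInit = 1L,
                      carriers = cm, params = params, extraCost = extraCost,
                      regionLabel = regionLabel, allowPartial = allowPartial)
  tr <- neuronTree(x = res$pos[, 1], y = res$pos[, 2], z = res$pos[, 3],
                   diameter = res$diam, region = res$region,
                   parent = res$parent)
  attr(tr, "carrierIndex") <- res$carrierOf[-1]
  attr(tr, "unconnected") <- res$unconnected
  tr
}

#' Grow a tree until a target branch-point count is reached
#'
#' Repeatedly samples an increasing number of carrier points from a density
#' field (fresh sub-seed each round) and grows a tree, returning the first
#' tree whose branch-point count reaches the target — the procedure used to
#' match synthetic trees to branch-point numbers observed in real cells.
#' The schedule starts at twice the target and increases by 10\% per round,
#' capped at 100 times the target.
#'
#' @param field a \code{FieldSpec}.
#' @param root root position.
#' @param targetBranchPoints required number of branch points (>= 0).
#' @param params a \code{GrowthParameters}.
#' @param seed base seed for carrier sampling.
#' @return a \code{NeuronTree} with attribute \code{finalN}, the carrier
#'   count that reached the target.
#' @export
growToBranchCount <- function(field, root, targetBranchPoints,
                              params = growthParameters(), seed = NULL) {
  stopifnot(targetBranchPoints >= 0)
  n <- 2 * targetBranchPoints
  cap <- 100 * max(targetBranchPoints, 1)
  k <- 0L
  repeat {
    pts <- sampleField(field, round(n), subSeed(seed, k))
    tr <- growTree(root, pts, params)
    bp <- sum(classifyNodes(tr) == "branch")
    if (bp >= targetBranchPoints) {
      attr(tr, "finalN") <- round(n)
      return(tr)
    }
    if (n >= cap)
      stop("target branch-point count unreachable within the carrier cap")
    n <- min(cap, max(n + 1, n * 1.1))
    k <- k + 1L
  }
}

#' Staged growth on a resampled scaffold
#'
#' Resamples an existing tree (stage one) to a fixed segment length so that
#' it offers regularly spaced attachment points, then continues greedy
#' growth over a second carrier set with path lengths measured from the
#' original root — the procedure used to grow apical tufts before oblique
#' dendrites, or thick primary dendrites before spiny branchlets.  Stage-two
#' nodes carry a distinct region label.
#'
#' @param stage1 a \code{NeuronTree}.
#' @param resampleDistance scaffold sampling distance, \eqn{\mu m}
#'   (e.g. 5).
#' @param carriers2 stage-two carrier points.
#' @param params a \code{GrowthParameters}.
#' @param regionLabel region code for stage-two nodes (default: one more
#'   than the largest stage-one label).
#' @return a \code{NeuronTree} containing scaffold and stage-two nodes.
#' @export
growStaged <- function(stage1, resampleDistance, carriers2,
                       params = growthParameters(),
                       regionLabel = NULL) {
  scaffold <- resampleTree(stage1, resampleDistance, conserveLength = TRUE)
  if (is.null(regionLabel)) regionLabel <- max(regions(scaffold)) + 1L
  cm <- asCarrierMatrix(carriers2)
  n0 <- nNodes(scaffold)
  res <- greedyEngine(initPos = xyz(scaffold),
                      initParent = parentIds(scaffold),
                      initDiam = diameters(scaffold),
                      initRegion = regions(scaffold),
                      initTree = rep(1L, n0),
                      pointIdInit = rep(0L, n0),
                      carriers = cm, params = params,
                      regionLabel = regionLabel)
  neuronTree(x = res$pos[, 1], y = res$pos[, 2], z = res$pos[, 3],
             diameter = res$diam, region = res$region, parent = res$parent)
}

#' Competitive growth of several trees over a shared carrier set
#'
#' All trees grow in one global greedy loop: at every step the globally
#' cheapest (tree, carrier, attachment) triple is connected, so trees claim
#' carriers one after the other and spatial tiling of the substrate emerges
#' automatically.  Every carrier ends up in exactly one tree.
#'
#' @param roots matrix of root positions (one row per tree).
#' @param carriers shared \code{CarrierPointSet} or matrix.
#' @param params a \code{GrowthParameters}.
#' @param extraCost optional pairwise cost matrix over point ids (root r =
#'   r, carrier j = nRoots + j).
#' @param allowPartial as in \code{\link{growTree}}.
#' @return list of \code{NeuronTree}s, one per root.
#' @export
growCompetitive <- function(roots, carriers, params = growthParameters(),
                            extraCost = NULL, allowPartial = FALSE) {
  roots <- as.matrix(roots)
  if (ncol(roots) == 2L) roots <- cbind(roots, 0)
  nR <- nrow(roots)
  stopifnot(nR >= 1L)
  cm <- asCarrierMatrix(carriers)
  res <- greedyEngine(initPos = roots,
                      initParent = rep(NA_integer_, nR),
                      initDiam = rep(1, nR), initRegion = rep(1L, nR),
                      initTree = seq_len(nR), pointIdInit = seq_len(nR),
                      carriers = cm, params = params, extraCost = extraCost,
                      allowPartial = allowPartial)
  lapply(seq_len(nR), function(t) {
    sel <- which(res$treeId == t)
    rank <- integer(res$n)
    rank[sel] <- seq_along(sel)
    par <- res$parent[sel]
    neuronTree(x = res$pos[sel, 1], y = res$pos[sel, 2], z = res$pos[sel, 3],
               diameter = res$diam[sel], region = res$region[sel],
               parent = ifelse(is.na(par), NA_integer_, rank[ifelse(is.na(par), 1L, par)]))
  })
}
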