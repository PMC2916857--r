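# Independent oracles, deliberately written without reference to the
# package internals they check.

# Prim's algorithm on the complete Euclidean graph over the given points;
# returns the total MST length.
primMSTLength <- function(points) {
  n <- nrow(points)
  if (n <= 1) return(0)
  inTree <- c(TRUE, rep(FALSE, n - 1))
  best <- sqrt(rowSums(sweep(points, 2, points[1, ])^2))
  total <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!inTree)
    j <- cand[which.min(best[cand])]
    total <- total + best[j]
    inTree[j] <- TRUE
    d <- sqrt(rowSums(sweep(points, 2, points[j, ])^2))
    upd <- !inTree & d < best
    best[upd] <- d[upd]
  }
  total
}

# brute-force Sholl: per radius, count sign changes of (dist - r) across edges
bruteSholl <- function(tree, radii) {
  m <- xyz(tree)
  root <- which(is.na(parentIds(tree)))
  dist <- sqrt(rowSums(sweep(m, 2, m[root, ])^2))
  p <- parentIds(tree)
  out <- integer(length(radii))
  for (q in seq_along(radii)) {
    r <- radii[q]
    cnt <- 0L
    for (i in seq_len(nNodes(tree))) {
      if (is.na(p[i])) next
      a <- dist[i] - r
      b <- dist[p[i]] - r
      if (min(a, b) <= 0 && max(a, b) > 0) cnt <- cnt + 1L
    }
    out[q] <- cnt
  }
  out
}

# replay a grown tree step by step and verify that every greedy choice
# minimized cost(p, v) = ||p - v|| + bf * (PL(v) + ||p - v||) over all
# unconnected carriers and admissible nodes at that step
replayIsOptimal <- function(tree, root, carriers, bf,
                            maxChildren = Inf, maxChildrenRoot = Inf,
                            tol = 1e-9) {
  carriers <- if (is(carriers, "CarrierPointSet")) carrierPoints(carriers)
              else as.matrix(carriers)
  ord <- attr(tree, "carrierIndex")
  m <- nrow(carriers)
  stopifnot(length(ord) == m)
  nodes <- matrix(c(root, 0)[1:3], 1, 3)
  pl <- 0
  nchild <- 0L
  for (step in seq_len(m)) {
    remaining <- ord[step:m]
    caps <- c(maxChildrenRoot, rep(maxChildren, nrow(nodes) - 1))
    admissible <- which(nchild < caps)
    # cost of every (remaining carrier, admissible node) pair
    bestAll <- Inf
    for (ci in remaining) {
      e <- sqrt(rowSums(sweep(nodes[admissible, , drop = FALSE], 2,
                              carriers[ci, ])^2))
      costs <- e * (1 + bf) + bf * pl[admissible]
      if (min(costs) < bestAll) bestAll <- min(costs)
    }
    # the executed attachment: carrier ord[step] onto its recorded parent
    v <- parentIds(tree)[step + 1L]
    e0 <- sqrt(sum((carriers[ord[step], ] - nodes[v, ])^2))
    chosenCost <- e0 * (1 + bf) + bf * pl[v]
    if (chosenCost > bestAll + tol) return(FALSE)
    nodes <- rbind(nodes, carriers[ord[step], ])
    pl <- c(pl, pl[v] + e0)
    nchild[v] <- nchild[v] + 1L
    nchild <- c(nchild, 0L)
  }
  TRUE
}

# sum of path-length values over a node's subtree, by brute enumeration
bruteSubtreeSum <- function(tree, node) {
  p <- parentIds(tree)
  pl <- pathLengthToRoot(tree)
  inSub <- function(i) {
    while (!is.na(i)) {
      if (i == node) return(TRUE)
      i <- p[i]
    }
    FALSE
  }
  sum(pl[vapply(seq_len(nNodes(tree)), inSub, logical(1))])
}

# distance from a point to a segment (for render/reconstruction checks)
pointSegmentDist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab * ab), 1e-12)
  t <- min(1, max(0, t))
  sqrt(sum((p - (a + t * ab))^2))
}

# distance from each point to the nearest edge of a tree
minEdgeDist <- function(points, tree) {
  m <- xyz(tree)
  par <- parentIds(tree)
  idx <- which(!is.na(par))
  apply(points, 1, function(p)
    min(vapply(idx, function(i)
      pointSegmentDist(p, m[par[i], ], m[i, ]), numeric(1))))
}
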