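## Branching statistics used for validation (branch order, Sholl, summary
## triplet) and population operations (region-wise scaling, density clouds).

#' Branch order of every node
#'
#' The branch order increases by one after each branch point on the way from
#' the root: a node's order is the number of branch points among its proper
#' ancestors (the root counts if it emits more than one stem).
#'
#' @param tree a \code{NeuronTree}.
#' @return integer vector; 0 along the unbranched stem.
#' @export
branchOrder <- function(tree) {
  p <- parentIds(tree)
  isBranch <- nChildren(tree) >= 2L
  ord <- integer(nNodes(tree))
  for (i in topoOrder(p)) if (!is.na(p[i]))
    ord[i] <- ord[p[i]] + as.integer(isBranch[p[i]])
  ord
}

#' Sholl intersection counts
#'
#' Counts the intersections of the tree with concentric spheres centred on
#' the root: for each radius, the number of edges whose two endpoint
#' distances from the root straddle the sphere (closed at the lower bound,
#' open at the upper, so tangent endpoints count once).
#'
#' @param tree a \code{NeuronTree}.
#' @param radii numeric vector of sphere radii (\eqn{\mu m}, > 0).
#' @return integer vector of intersection counts, one per radius.
#' @export
sholl <- function(tree, radii) {
  if (any(radii <= 0)) stop("radii must be positive")
  m <- xyz(tree)
  root <- rootIndex(tree)
  r <- rowDist(m, m[root, ])
  p <- parentIds(tree)
  idx <- which(!is.na(p))
  lo <- pmin(r[idx], r[p[idx]])
  hi <- pmax(r[idx], r[p[idx]])
  vapply(radii, function(rad) sum(lo <= rad & hi > rad), integer(1))
}

#' Morphometric summary of a tree
#'
#' The summary triplet used to fit growth parameters against a reference
#' cell — total cable length, number of branch points, mean path length to
#' the root — plus branch-order, path-length and Sholl distributions.
#'
#' @param tree a \code{NeuronTree}.
#' @param pathBin path-length (and Sholl radius) bin width in \eqn{\mu m}.
#' @return a list of class \code{"morphSummary"} with elements
#'   \code{totalCableLength}, \code{nBranchPoints}, \code{meanPathLength},
#'   \code{branchOrderHist}, \code{pathLengthHist}, \code{sholl}.
#' @export
morphSummary <- function(tree, pathBin = 10) {
  pl <- pathLengthToRoot(tree)
  cls <- classifyNodes(tree)
  bo <- branchOrder(tree)
  maxExtent <- max(rowDist(xyz(tree), xyz(tree)[rootIndex(tree), ]))
  radii <- seq(pathBin, max(pathBin, ceiling(maxExtent / pathBin) * pathBin),
               by = pathBin)
  brk <- seq(0, max(pathBin, ceiling(max(pl) / pathBin) * pathBin), by = pathBin)
  out <- list(
    totalCableLength = totalCableLength(tree),
    nBranchPoints = sum(cls == "branch"),
    meanPathLength = mean(pl),
    branchOrderHist = tabulate(bo + 1L, nbins = max(bo) + 1L),
    pathLengthHist = as.integer(table(cut(pl, brk, include.lowest = TRUE))),
    sholl = data.frame(radius = radii, count = sholl(tree, radii)))
  class(out) <- "morphSummary"
  out
}

#' @export
print.morphSummary <- function(x, ...) {
  cat(sprintf("total cable length: %.1f um | branch points: %d | mean path length: %.1f um\n",
              x$totalCableLength, x$nBranchPoints, x$meanPathLength))
  invisible(x)
}

#' Match a tree against a reference summary
#'
#' Applies the per-criterion tolerances used to select balancing factor and
#' carrier-point count: total cable length within 200 \eqn{\mu m}, branch
#' points within 5, mean path length within 3 \eqn{\mu m} (defaults).
#'
#' @param tree a \code{NeuronTree} or a \code{morphSummary}.
#' @param reference a \code{morphSummary} (or \code{NeuronTree}) to match.
#' @param tolerances named numeric: \code{cable}, \code{branchPoints},
#'   \code{meanPath}.
#' @return named logical, one entry per criterion.
#' @export
matchSummary <- function(tree, reference,
                         tolerances = c(cable = 200, branchPoints = 5,
                                        meanPath = 3)) {
  s <- if (inherits(tree, "morphSummary")) tree else morphSummary(tree)
  r <- if (inherits(reference, "morphSummary")) reference else morphSummary(reference)
  c(cable = abs(s$totalCableLength - r$totalCableLength) <= tolerances[["cable"]],
    branchPoints = abs(s$nBranchPoints - r$nBranchPoints) <= tolerances[["branchPoints"]],
    meanPath = abs(s$meanPathLength - r$meanPathLength) <= tolerances[["meanPath"]])
}

#' Scale a population of trees to the mean limits of each region
#'
#' For every region label and axis, each tree's node coordinates are affinely
#' mapped so that the tree's region bounding interval coincides with the mean
#' bounding interval of that region across the population (size
#' normalization; cells should already be centred on their somata and
#' rotated into a common frame).  Idempotent on an already-scaled population.
#'
#' @param trees list of \code{NeuronTree}s with region labels.
#' @return list with elements \code{trees} (the scaled population) and
#'   \code{spec}, a data.frame of mean and SD bounding limits per region and
#'   axis (the spanning-field specification).
#' @export
scaleToMeanLimits <- function(trees) {
  if (!length(trees)) stop("empty population")
  regs <- sort(unique(unlist(lapply(trees, regions))))
  axes <- c("x", "y", "z")
  lim <- array(NA_real_, dim = c(length(trees), length(regs), 3, 2))
  for (t in seq_along(trees)) {
    m <- xyz(trees[[t]])
    rg <- regions(trees[[t]])
    for (g in seq_along(regs)) {
      sel <- rg == regs[g]
      if (!any(sel)) next
      for (a in 1:3) lim[t, g, a, ] <- range(m[sel, a])
    }
  }
  meanLim <- apply(lim, c(2, 3, 4), mean, na.rm = TRUE)
  sdLim <- apply(lim, c(2, 3, 4), sd, na.rm = TRUE)
  scaled <- lapply(seq_along(trees), function(t) {
    tr <- trees[[t]]
    nd <- tr@nodes
    rg <- regions(tr)
    for (g in seq_along(regs)) {
      sel <- rg == regs[g]
      if (!any(sel)) next
      for (a in 1:3) {
        lo <- lim[t, g, a, 1]; hi <- lim[t, g, a, 2]
        mlo <- meanLim[g, a, 1]; mhi <- meanLim[g, a, 2]
        v <- nd[[axes[a]]][sel]
        nd[[axes[a]]][sel] <- if (hi > lo)
          mlo + (v - lo) * (mhi - mlo) / (hi - lo)
        else v - lo + (mlo + mhi) / 2   # degenerate extent: recentre
      }
    }
    new("NeuronTree", nodes = nd, parent = tr@parent)
  })
  spec <- do.call(rbind, lapply(seq_along(regs), function(g)
    data.frame(region = regs[g], axis = axes,
               meanMin = meanLim[g, , 1], meanMax = meanLim[g, , 2],
               sdMin = sdLim[g, , 1], sdMax = sdLim[g, , 2])))
  list(trees = scaled, spec = spec)
}

#' Empirical density cloud of points or topological points of trees
#'
#' Bins points (or the branch and termination points of one or more trees)
#' on a regular grid, applies a one-bin Gaussian smoothing and renormalizes,
#' producing a nonnegative density grid of total mass 1 that can be sampled
#' by \code{\link{sampleEmpirical}}.
#'
#' @param x an n x 2/3 matrix of points, a \code{NeuronTree}, or a list of
#'   \code{NeuronTree}s (topological points are pooled).
#' @param binSize bin width in \eqn{\mu m} (default 10).
#' @param smoothing Gaussian smoothing SD in bins (default 1; 0 disables).
#' @return list of class \code{"densityGrid"}: \code{grid} (3D array summing
#'   to 1), \code{origin}, \code{binSize}.
#' @export
densityCloud <- function(x, binSize = 10, smoothing = 1) {
  pts <- topoPointsOf(x)
  if (!nrow(pts)) stop("no points to bin")
  lo <- apply(pts, 2, min) - binSize / 2
  hi <- apply(pts, 2, max) + binSize / 2
  nb <- pmax(1L, ceiling((hi - lo) / binSize))
  idx <- sapply(1:3, function(a)
    pmin(nb[a], pmax(1L, floor((pts[, a] - lo[a]) / binSize) + 1L)))
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1)
  grid <- array(0, dim = nb)
  flat <- (idx[, 3] - 1L) * nb[1] * nb[2] + (idx[, 2] - 1L) * nb[1] + idx[, 1]
  tab <- table(flat)
  grid[as.integer(names(tab))] <- as.integer(tab)
  if (smoothing > 0) grid <- gaussianSmooth3D(grid, smoothing)
  grid <- grid / sum(grid)
  structure(list(grid = grid, origin = lo, binSize = binSize),
            class = "densityGrid")
}

topoPointsOf <- function(x) {
  asPts <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) == 2L) m <- cbind(m, 0)
    m[, 1:3, drop = FALSE]
  }
  if (is.matrix(x) || is.data.frame(x)) return(asPts(x))
  if (is(x, "NeuronTree")) x <- list(x)
  do.call(rbind, lapply(x, function(tr) {
    cls <- classifyNodes(tr)
    xyz(tr)[cls %in% c("branch", "termination"), , drop = FALSE]
  }))
}

# Separable Gaussian smoothing of a 3D array (kernel radius 3 sigma);
# sigma may be per-axis (entries <= 0 skip the axis).
gaussianSmooth3D <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  convAxis <- function(a, axis) {
    s <- sigma[axis]
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    k <- k / sum(k)
    n <- dim(a)[axis]
    out <- array(0, dim(a))
    for (off in -r:r) {
      w <- k[off + r + 1]
      src <- pmin(pmax(seq_len(n) + off, 1L), n)   # replicate-pad
      out <- out + w * switch(axis,
        a[src, , , drop = FALSE], a[, src, , drop = FALSE], a[, , src, drop = FALSE])
    }
    out
  }
  convAxis(convAxis(convAxis(a, 1L), 2L), 3L)
}

## ---- convex hull overlap (tiling metric) ----------------------------------

#' Overlap area of the planar convex hulls of two trees
#'
#' The xy convex hulls of the two node sets are intersected
#' (Sutherland-Hodgman clipping of one convex polygon by the other) and the
#' intersection area returned; used to quantify dendritic tiling under
#' competitive growth.
#'
#' @param a,b \code{NeuronTree}s, or n x 2 coordinate matrices.
#' @return overlap area in \eqn{\mu m^2}.
#' @export
hullOverlapArea <- function(a, b) {
  ptsOf <- function(x) if (is(x, "NeuronTree")) xyz(x)[, 1:2, drop = FALSE]
                       else as.matrix(x)[, 1:2, drop = FALSE]
  pa <- ptsOf(a); pb <- ptsOf(b)
  if (nrow(pa) < 3L || nrow(pb) < 3L) return(0)
  ha <- pa[rev(grDevices::chull(pa)), , drop = FALSE]  # counter-clockwise
  hb <- pb[rev(grDevices::chull(pb)), , drop = FALSE]
  inter <- clipConvex(ha, hb)
  if (is.null(inter) || nrow(inter) < 3L) return(0)
  polygonArea(inter)
}

# Sutherland-Hodgman: clip convex polygon subj by convex polygon clip
# (both counter-clockwise).
clipConvex <- function(subj, clip) {
  out <- subj
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    A <- clip[i, ]; B <- clip[if (i == nc) 1L else i + 1L, ]
    inside <- function(p) (B[1] - A[1]) * (p[2] - A[2]) -
                          (B[2] - A[2]) * (p[1] - A[1]) >= -1e-12
    res <- matrix(numeric(0), 0, 2)
    n <- nrow(out)
    for (j in seq_len(n)) {
      P <- out[j, ]; Q <- out[if (j == n) 1L else j + 1L, ]
      pin <- inside(P); qin <- inside(Q)
      if (pin) res <- rbind(res, P)
      if (xor(pin, qin)) {
        d1 <- (B[1] - A[1]) * (P[2] - A[2]) - (B[2] - A[2]) * (P[1] - A[1])
        d2 <- (B[1] - A[1]) * (Q[2] - A[2]) - (B[2] - A[2]) * (Q[1] - A[1])
        t <- d1 / (d1 - d2)
        res <- rbind(res, P + t * (Q - P))
      }
    }
    out <- res
  }
  out
}

polygonArea <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}
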