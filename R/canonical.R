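## Canonical (unique) tree representation: hierarchical label sorting,
## equidistant resampling, the electrotonic-equivalent layout and the
## one-dimensional "topological gene" encoding.

#' Topological depth of every node
#'
#' The score used to order siblings during label sorting: for each node, the
#' sum of the path-length values over all nodes of its subtree (the node
#' itself included, so a terminal scores its own path length).
#'
#' @param tree a \code{NeuronTree}.
#' @return numeric vector of per-node scores.
#' @export
topologicalDepth <- function(tree) {
  p <- parentIds(tree)
  pl <- pathLengthToRoot(tree)
  depth <- pl
  for (i in rev(topoOrder(p))) if (!is.na(p[i])) depth[p[i]] <- depth[p[i]] + depth[i]
  depth
}

# Canonical node order: depth-first from the root, siblings by decreasing
# topological depth; exact ties broken by larger subtree size, then by the
# smaller minimum original node index in the subtree (total determinism).
canonicalOrder <- function(tree) {
  p <- parentIds(tree)
  kids <- childrenList(p)
  depth <- topologicalDepth(tree)
  n <- nNodes(tree)
  size <- rep(1L, n)
  minidx <- seq_len(n)
  for (i in rev(topoOrder(p))) if (!is.na(p[i])) {
    size[p[i]] <- size[p[i]] + size[i]
    minidx[p[i]] <- min(minidx[p[i]], minidx[i])
  }
  ord <- integer(n)
  stack <- rootIndex(tree)
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ord[k] <- v
    ch <- kids[[v]]
    if (length(ch) > 1L) {
      o <- order(-depth[ch], -size[ch], minidx[ch])
      ch <- ch[o]
    }
    if (length(ch)) stack <- c(stack, rev(ch))   # LIFO: first child on top
  }
  ord
}

#' Canonically relabel a tree (label sorting)
#'
#' Produces the unique labelling of the tree: labels are hierarchical (every
#' child's label exceeds its parent's), every sub-tree occupies a contiguous
#' label range, and at each branch point the sub-tree with the larger
#' topological depth (sum of path-length values over its nodes) is labelled
#' first.  Geometry is untouched; the operation is idempotent and invariant
#' to permutations of the input node order.
#'
#' @param tree a \code{NeuronTree}.
#' @return a relabelled \code{NeuronTree} whose root has label 1.
#' @export
sortLabels <- function(tree) {
  ord <- canonicalOrder(tree)
  rank <- integer(nNodes(tree))
  rank[ord] <- seq_along(ord)
  p <- parentIds(tree)[ord]
  newpar <- ifelse(is.na(p), NA_integer_, rank[ifelse(is.na(p), 1L, p)])
  new("NeuronTree", nodes = `rownames<-`(tree@nodes[ord, ], NULL),
      parent = as.integer(newpar))
}

isSorted <- function(tree) identical(canonicalOrder(tree), seq_len(nNodes(tree)))

#' Equidistant resampling of a tree
#'
#' Redistributes nodes at equal inter-node distances while keeping every
#' topological point (root, branch points, terminals).  Each branch — the
#' cable between two topological points — is traversed from the root outward
#' and new nodes are placed at multiples of the sampling distance along its
#' path; the intervening continuation nodes are removed while connectivity
#' is maintained.  Straightening a wriggly path into chords can only shorten
#' segments, so without length conservation all edges are chords of length
#' at most \code{distance}.
#'
#' With \code{conserveLength = TRUE} the node count of each branch is the
#' compensated nearest-integer rounding of its arc length over the sampling
#' distance — for a terminal branch this is exactly "lengthen by half the
#' sampling distance, then cut at the last multiple", and a running
#' remainder carries rounding residue between branches — and every
#' straightened segment is then radially elongated about its parent node
#' (processed root-outward in label order) to the full sampling distance.
#' All edges then measure exactly \code{distance} and the total cable length
#' is conserved to within half a sampling distance per terminal branch.
#'
#' @param tree a \code{NeuronTree}.
#' @param distance sampling distance in \eqn{\mu m} (> 0).
#' @param conserveLength conserve total cable length (default FALSE).
#' @return a canonically labelled, resampled \code{NeuronTree}.
#' @export
resampleTree <- function(tree, distance, conserveLength = FALSE) {
  if (!is.numeric(distance) || length(distance) != 1L || distance <= 0)
    stop("sampling distance must be a positive number")
  d <- distance
  tol <- 1e-9 * d
  tr <- sortLabels(tree)
  pos <- xyz(tr)
  par <- parentIds(tr)
  dia <- diameters(tr)
  reg <- regions(tr)
  nc <- nChildren(tr)
  n <- nNodes(tr)
  topo <- nc != 1L
  topo[1L] <- TRUE
  # nearest ancestral topological point (label order: parents first)
  anc <- integer(n)
  for (i in seq_len(n)[-1])
    anc[i] <- if (topo[par[i]]) par[i] else anc[par[i]]

  cap <- max(16L, ceiling(totalCableLength(tr) / d) + sum(topo) + 8L)
  NX <- numeric(cap); NY <- numeric(cap); NZ <- numeric(cap)
  ND <- numeric(cap); NR <- integer(cap); NP <- integer(cap)
  nn <- 1L
  NX[1] <- pos[1, 1]; NY[1] <- pos[1, 2]; NZ[1] <- pos[1, 3]
  ND[1] <- dia[1]; NR[1] <- reg[1]; NP[1] <- NA_integer_
  addNode <- function(p3, dm, rg, parent) {
    nn <<- nn + 1L
    if (nn > length(NX)) {
      extra <- length(NX)
      NX <<- c(NX, numeric(extra)); NY <<- c(NY, numeric(extra))
      NZ <<- c(NZ, numeric(extra)); ND <<- c(ND, numeric(extra))
      NR <<- c(NR, integer(extra)); NP <<- c(NP, integer(extra))
    }
    NX[nn] <<- p3[1]; NY[nn] <<- p3[2]; NZ[nn] <<- p3[3]
    ND[nn] <<- dm; NR[nn] <<- rg; NP[nn] <<- parent
    nn
  }
  # position/diameter at arc t along a polyline given by node indices
  interpAt <- function(chain, cum, t) {
    k <- findInterval(t, cum, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(chain) - 1L)
    seg <- cum[k + 1L] - cum[k]
    f <- if (seg > 0) (t - cum[k]) / seg else 0
    a <- chain[k]; b <- chain[k + 1L]
    list(p = pos[a, ] + f * (pos[b, ] - pos[a, ]),
         dm = dia[a] + f * (dia[b] - dia[a]), rg = reg[b])
  }

  newIndex <- integer(n)      # topological point -> new node index
  newIndex[1L] <- 1L
  residual <- 0               # running cable-length rounding residue
  # branches in canonical order of their end topological point
  for (t in which(topo & seq_len(n) > 1L)) {
    a <- anc[t]
    chain <- t
    v <- par[t]
    while (v != a) { chain <- c(chain, v); v <- par[v] }
    chain <- rev(c(chain, a))                 # a ... t along the branch
    lens <- vapply(seq_len(length(chain) - 1L), function(k)
      vnorm(pos[chain[k + 1L], ] - pos[chain[k], ]), numeric(1))
    cum <- c(0, cumsum(lens))
    arc <- cum[length(cum)]
    np <- newIndex[a]
    if (conserveLength) {
      ns <- max(1L, as.integer(round((arc - residual) / d)))
      residual <- residual + ns * d - arc
      for (j in seq_len(ns)) {
        q <- interpAt(chain, cum, arc * j / ns)
        np <- addNode(q$p, q$dm, q$rg, np)
      }
    } else {
      arcs <- seq(d, arc + tol, by = d)
      arcs <- arcs[arcs <= arc + tol]
      if (length(arcs) && arc - arcs[length(arcs)] <= tol)
        arcs[length(arcs)] <- arc
      if (!length(arcs) || arcs[length(arcs)] < arc - tol)
        arcs <- c(arcs, arc)                  # keep the topological point
      for (t2 in arcs) {
        q <- interpAt(chain, cum, min(t2, arc))
        np <- addNode(q$p, q$dm, q$rg, np)
      }
    }
    newIndex[t] <- np
  }

  nx <- NX[seq_len(nn)]; ny <- NY[seq_len(nn)]; nz <- NZ[seq_len(nn)]
  nd <- ND[seq_len(nn)]; nr <- NR[seq_len(nn)]
  npar <- NP[seq_len(nn)]; npar[1] <- NA_integer_

  if (conserveLength && nn > 1L) {
    # radial elongation about the parent to the full sampling distance,
    # processed root-outward (nodes were created parents-first)
    bx <- nx; by <- ny; bz <- nz
    dirp <- matrix(0, nn, 3)
    for (i in 2:nn) {
      p <- npar[i]
      u <- c(bx[i] - bx[p], by[i] - by[p], bz[i] - bz[p])
      cn <- vnorm(u)
      u <- if (cn > 1e-12) u / cn else dirp[p, ]
      if (all(u == 0)) u <- c(0, 0, 1)
      dirp[i, ] <- u
      nx[i] <- nx[p] + d * u[1]
      ny[i] <- ny[p] + d * u[2]
      nz[i] <- nz[p] + d * u[3]
    }
  }

  out <- neuronTree(x = nx, y = ny, z = nz, diameter = nd, region = nr,
                    parent = npar)
  sortLabels(out)
}

#' Electrotonic-equivalent planar layout
#'
#' Rearranges node positions into a unique circular dendrogram: every edge
#' keeps its original length, and each node is placed at its parent's
#' position displaced along the direction whose angle grows monotonically
#' with the node's canonical label (\eqn{\theta = \pi (\ell - 1) / (N - 1)}
#' over a half circle, the root at the origin).  Path lengths to the root —
#' and hence the passive electrotonic signature, at uniform diameter — are
#' unchanged; the layout is a deterministic function of the topological gene
#' plus branch lengths.
#'
#' @param tree a \code{NeuronTree}.
#' @return a \code{NeuronTree} with rearranged planar coordinates.
#' @export
equivalentTree <- function(tree) {
  tr <- sortLabels(tree)
  n <- nNodes(tr)
  len <- segmentLengths(tr)
  p <- parentIds(tr)
  theta <- if (n > 1) pi * (seq_len(n) - 1) / (n - 1) else 0
  nx <- numeric(n); ny <- numeric(n)
  for (i in seq_len(n)[-1])
    { nx[i] <- nx[p[i]] + len[i] * cos(theta[i]); ny[i] <- ny[p[i]] + len[i] * sin(theta[i]) }
  nd <- tr@nodes
  nd$x <- nx; nd$y <- ny; nd$z <- 0
  new("NeuronTree", nodes = nd, parent = tr@parent)
}

#' Topological gene: canonical one-dimensional encoding of a tree
#'
#' Each branch (the cable between two topological points) is listed in
#' canonical label order as its metric length followed by \code{"B"} if it
#' ends in a branch point or \code{"T"} if it ends in a termination.  For
#' binary trees the string determines topology and branch lengths completely,
#' so the electrotonic signature (at known diameters) can be reconstructed
#' from it alone.
#'
#' @param tree a \code{NeuronTree}.
#' @param sort canonically relabel first (default TRUE; set FALSE if the tree
#'   is already canonically labelled and that labelling must be kept).
#' @return data.frame with columns \code{length} (\eqn{\mu m}) and
#'   \code{terminator} (\code{"B"}/\code{"T"}).
#' @export
topologicalGene <- function(tree, sort = TRUE) {
  tr <- if (sort) sortLabels(tree) else tree
  p <- parentIds(tr)
  pl <- pathLengthToRoot(tr)
  nc <- nChildren(tr)
  n <- nNodes(tr)
  topo <- nc != 1L                       # branch or termination (or bare root)
  topo[1L] <- TRUE                       # root counts as a topological point
  # nearest ancestral topological point, via label order (parents first)
  anc <- integer(n)
  for (i in seq_len(n)[-1])
    anc[i] <- if (topo[p[i]]) p[i] else anc[p[i]]
  sel <- which(topo & seq_len(n) > 1L)
  data.frame(length = pl[sel] - pl[anc[sel]],
             terminator = ifelse(nc[sel] >= 2L, "B", "T"),
             stringsAsFactors = FALSE)
}

#' Rebuild a tree from its topological gene
#'
#' Reconstructs a binary tree whose topological gene equals the input: the
#' gene entries are consumed in order, each \code{"B"} opening a branch point
#' with two pending child slots and each \code{"T"} closing a terminal.
#' Coordinates are assigned by the electrotonic-equivalent layout, so two
#' identical genes always yield identical trees.
#'
#' @param gene data.frame with columns \code{length} and \code{terminator},
#'   as produced by \code{\link{topologicalGene}}.
#' @return a \code{NeuronTree} (labels in build order, which is the gene's
#'   canonical order).
#' @export
treeFromGene <- function(gene) {
  nb <- nrow(gene)
  if (nb < 1L) stop("empty gene")
  if (!all(gene$terminator %in% c("B", "T")))
    stop("gene terminators must be 'B' or 'T'")
  if (sum(gene$terminator == "T") != sum(gene$terminator == "B") + 1L)
    stop("unbalanced gene: need #T = #B + 1 for a binary tree")
  if (any(gene$length <= 0)) stop("gene branch lengths must be positive")
  n <- nb + 1L
  parent <- rep(NA_integer_, n)
  len <- numeric(n)
  stackNode <- c(1L); stackSlots <- c(1L)   # root emits a single stem
  for (r in seq_len(nb)) {
    if (!length(stackNode)) stop("unbalanced gene: branch after all terminals closed")
    top <- length(stackNode)
    att <- stackNode[top]
    stackSlots[top] <- stackSlots[top] - 1L
    if (stackSlots[top] == 0L) { stackNode <- stackNode[-top]; stackSlots <- stackSlots[-top] }
    node <- r + 1L
    parent[node] <- att
    len[node] <- gene$length[r]
    if (gene$terminator[r] == "B") {
      stackNode <- c(stackNode, node); stackSlots <- c(stackSlots, 2L)
    }
  }
  if (length(stackNode)) stop("unbalanced gene: unclosed branch points remain")
  theta <- if (n > 1) pi * (seq_len(n) - 1) / (n - 1) else 0
  x <- numeric(n); y <- numeric(n)
  for (i in 2:n) {
    x[i] <- x[parent[i]] + len[i] * cos(theta[i])
    y[i] <- y[parent[i]] + len[i] * sin(theta[i])
  }
  neuronTree(x = x, y = y, z = 0, diameter = 1,
             region = c(1L, rep(3L, n - 1L)), parent = parent)
}
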