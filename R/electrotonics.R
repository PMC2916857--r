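## Steady-state passive electrotonics: conductance matrix construction,
## signature by matrix inversion, and the compartment-size statistic.

# Per-edge axial conductance (S) and per-node lumped membrane area (cm^2).
# Edge diameter is the mean of the two node diameters; each node receives
# half the lateral cylinder area of every adjacent edge.  Units: inputs in
# um, converted to cm here and nowhere else.
edgeQuantities <- function(tree, params) {
  p <- parentIds(tree)
  idx <- which(!is.na(p))
  len_um <- segmentLengths(tree)[idx]
  if (any(len_um == 0))
    stop("zero-length edge: resample the tree before electrotonic analysis")
  dia <- diameters(tree)
  if (any(dia <= 0)) stop("all diameters must be positive")
  d_um <- (dia[idx] + dia[p[idx]]) / 2
  L <- len_um * 1e-4
  d <- d_um * 1e-4
  gax <- pi * d^2 / (4 * params@ra * L)
  halfArea <- pi * d * L / 2
  area <- numeric(nNodes(tree))
  for (k in seq_along(idx)) {
    area[idx[k]] <- area[idx[k]] + halfArea[k]
    area[p[idx[k]]] <- area[p[idx[k]]] + halfArea[k]
  }
  list(child = idx, parent = p[idx], gax = gax, area = area)
}

#' Passive conductance matrix of a tree
#'
#' Builds the node-by-node conductance matrix (Siemens): off-diagonal entries
#' are minus the axial conductance of the connecting edge (cylinder
#' \eqn{g = \pi d^2 / (4 R_a L)}, edge diameter the mean of its two node
#' diameters), and the diagonal holds the sum of adjacent axial conductances
#' plus the node's membrane leak conductance (lumped membrane area over
#' \eqn{R_m}; each node owns half the lateral area of each adjacent edge).
#' Sealed-end boundary conditions are implicit.  The matrix is symmetric and
#' strictly diagonally dominant (every node leaks), hence positive definite.
#'
#' @param tree a \code{NeuronTree} with positive diameters and no zero-length
#'   edges (resample first if needed).
#' @param params a \code{\link{passiveParameters}} object.
#' @return dense numeric matrix (S), node order = input node order.
#' @export
conductanceMatrix <- function(tree, params = passiveParameters()) {
  n <- nNodes(tree)
  eq <- edgeQuantities(tree, params)
  G <- matrix(0, n, n)
  for (k in seq_along(eq$child)) {
    i <- eq$child[k]; j <- eq$parent[k]; g <- eq$gax[k]
    G[i, j] <- G[i, j] - g
    G[j, i] <- G[j, i] - g
    G[i, i] <- G[i, i] + g
    G[j, j] <- G[j, j] + g
  }
  diag(G) <- diag(G) + eq$area / params@rm
  G
}

#' Electrotonic signature of a tree
#'
#' Inverts the passive conductance matrix to obtain the node-by-node
#' steady-state potential matrix in mV: entry (i, j) is the potential at
#' node i when \code{params@i} nA is injected at node j (current transfer).
#' The matrix is symmetric by reciprocity and attains each column's maximum
#' on the diagonal.
#'
#' @inheritParams conductanceMatrix
#' @return an \code{ElectrotonicSignature}.
#' @export
electrotonicSignature <- function(tree, params = passiveParameters()) {
  G <- conductanceMatrix(tree, params)
  Vinv <- tryCatch(solve(G), error = function(e)
    stop("conductance matrix is singular (is membrane resistivity finite?)"))
  # solve(G) in S^-1 = Ohm; x nA -> nV; report mV
  V <- Vinv * params@i * 1e-6
  V <- (V + t(V)) / 2   # enforce exact symmetry against round-off
  new("ElectrotonicSignature", V = V, parameters = params)
}

# Cable length (um) assigned to each node: half of every adjacent edge.
# Sums to the total cable length.
nodeCableLength <- function(tree) {
  p <- parentIds(tree)
  idx <- which(!is.na(p))
  len <- segmentLengths(tree)[idx]
  out <- numeric(nNodes(tree))
  for (k in seq_along(idx)) {
    out[idx[k]] <- out[idx[k]] + len[k] / 2
    out[p[idx[k]]] <- out[p[idx[k]]] + len[k] / 2
  }
  out
}

#' Mean electrotonic compartment size
#'
#' For every injection node j, sums the cable length assigned to the nodes
#' whose steady-state deflection reaches at least \code{threshold} (default
#' 60\%) of the maximal deflection for that injection, then averages over all
#' injection sites.  An electrically tight tree approaches the total cable
#' length; strongly compartmentalized trees (grown with a high balancing
#' factor) give smaller values.
#'
#' @inheritParams conductanceMatrix
#' @param threshold fraction of the maximal potential deflection (in (0, 1]).
#' @param signature optionally, a precomputed \code{ElectrotonicSignature}.
#' @return mean compartment size in \eqn{\mu m}.
#' @export
compartmentSize <- function(tree, params = passiveParameters(),
                            threshold = 0.6, signature = NULL) {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  if (is.null(signature)) signature <- electrotonicSignature(tree, params)
  V <- potentials(signature)
  len <- nodeCableLength(tree)
  vmax <- apply(V, 2, max)
  mean(colSums(len * (V >= rep(threshold * vmax, each = nrow(V)))))
}
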