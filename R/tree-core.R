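## Elementary topological and geometric queries on NeuronTree objects, and
## SWC persistence.

#' @rdname validateTree
#' @export
setMethod("validateTree", "NeuronTree", function(object, ...) {
  nd <- object@nodes
  treeDiagnostics(nd$x, nd$y, nd$z, nd$diameter, object@parent, warnings = TRUE)
})

#' @rdname validateTree
#' @export
setMethod("validateTree", "data.frame", function(object, ...) {
  diam <- if ("diameter" %in% names(object)) object$diameter else NULL
  treeDiagnostics(object$x, object$y,
                  if ("z" %in% names(object)) object$z else rep(0, nrow(object)),
                  diam, as.integer(object$parent), warnings = TRUE)
})

#' Number of children of each node
#'
#' @param tree a \code{NeuronTree}.
#' @return integer vector, children count per node.
#' @export
nChildren <- function(tree) {
  tabulate(parentIds(tree)[!is.na(parentIds(tree))], nbins = nNodes(tree))
}

#' Classify nodes as root / continuation / branch / termination
#'
#' Branch points and termination points are the topological points of a tree;
#' continuation points lie between them along a branch.
#'
#' @param tree a \code{NeuronTree}.
#' @return factor with levels \code{root}, \code{continuation}, \code{branch},
#'   \code{termination}; branch-point degree is available via
#'   \code{\link{nChildren}}.
#' @export
classifyNodes <- function(tree) {
  nc <- nChildren(tree)
  cls <- ifelse(nc == 0L, "termination",
                ifelse(nc == 1L, "continuation", "branch"))
  cls[rootIndex(tree)] <- "root"
  factor(cls, levels = c("root", "continuation", "branch", "termination"))
}

#' Per-edge Euclidean segment lengths
#'
#' @param tree a \code{NeuronTree}.
#' @return numeric vector of length \code{nNodes(tree)}; entry i is the length
#'   (\eqn{\mu m}) of the edge from node i's parent to node i, 0 at the root.
#' @export
segmentLengths <- function(tree) {
  p <- parentIds(tree)
  m <- xyz(tree)
  len <- numeric(nNodes(tree))
  idx <- which(!is.na(p))
  if (length(idx))
    len[idx] <- sqrt(rowSums((m[idx, , drop = FALSE] -
                                m[p[idx], , drop = FALSE])^2))
  len
}

#' Cumulative path length from the root to each node
#'
#' The path length along the tree is the conduction-time proxy of the growth
#' model's second cost term.
#'
#' @param tree a \code{NeuronTree}.
#' @return numeric vector (\eqn{\mu m}); 0 at the root.
#' @export
pathLengthToRoot <- function(tree) {
  p <- parentIds(tree)
  len <- segmentLengths(tree)
  pl <- numeric(nNodes(tree))
  for (i in topoOrder(p)) if (!is.na(p[i])) pl[i] <- pl[p[i]] + len[i]
  pl
}

#' Total cable length of a tree
#'
#' @param tree a \code{NeuronTree}.
#' @return total length in \eqn{\mu m} (sum of all segment lengths).
#' @export
totalCableLength <- function(tree) sum(segmentLengths(tree))

#' Sparse adjacency matrix of the directed tree
#'
#' Entry (i, j) is 1 iff node j is the direct parent of node i (edges directed
#' away from the root), so every row except the root's sums to 1 and the
#' number of nonzeros equals the edge count \eqn{N - 1}.
#'
#' @param tree a \code{NeuronTree}.
#' @return a sparse 0/1 \code{\link[Matrix]{sparseMatrix}}.
#' @export
adjacencyMatrix <- function(tree) {
  n <- nNodes(tree)
  p <- parentIds(tree)
  idx <- which(!is.na(p))
  Matrix::sparseMatrix(i = idx, j = p[idx], x = 1, dims = c(n, n))
}

## ---- SWC I/O --------------------------------------------------------------

#' Read a neuronal reconstruction from an SWC file
#'
#' SWC is the standard 7-column whitespace-separated text format for neuronal
#' morphologies: id, type, x, y, z, radius, parent (-1 for the root), with
#' \code{#} comment lines.  Note SWC stores radii; \code{NeuronTree} stores
#' diameters (= 2 radius).
#'
#' @param path file path.
#' @return a \code{NeuronTree}.
#' @export
readSWC <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("SWC file contains no records: ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("malformed SWC line (expected 7 columns): ",
         lines[which(nf != 7L)[1L]])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (any(!is.finite(m[, c(1:6)])))
    stop("malformed SWC numeric field in ", path)
  ids <- as.integer(m[, 1])
  if (anyDuplicated(ids)) stop("duplicate node ids in SWC file")
  par_raw <- as.integer(m[, 7])
  lookup <- integer(max(ids))
  lookup[ids] <- seq_along(ids)
  parent <- rep(NA_integer_, length(ids))
  has_par <- par_raw != -1L
  if (any(has_par)) {
    unknown <- has_par & (par_raw < 1L | par_raw > max(ids) |
                            lookup[pmax(par_raw, 1L)] == 0L)
    if (any(unknown))
      stop("SWC parent references unknown id: ", par_raw[which(unknown)[1L]])
    parent[has_par] <- lookup[par_raw[has_par]]
  }
  if (sum(!has_par) != 1L) stop("SWC file must contain exactly one root")
  neuronTree(x = m[, 3], y = m[, 4], z = m[, 5], diameter = 2 * m[, 6],
             region = as.integer(m[, 2]), parent = parent)
}

#' Write a NeuronTree to an SWC file
#'
#' Nodes are written in an order in which every parent precedes its children
#' (SWC convention); ids are 1-based and contiguous.  Roundtrip through
#' \code{readSWC} preserves topology, coordinates and diameters to printed
#' precision.
#'
#' @param tree a \code{NeuronTree}.
#' @param path output file path.
#' @param digits printed coordinate precision (default 6).
#' @return invisibly, the path.
#' @export
writeSWC <- function(tree, path, digits = 6) {
  ord <- topoOrder(parentIds(tree))
  rank <- integer(nNodes(tree))
  rank[ord] <- seq_along(ord)
  nd <- tree@nodes[ord, ]
  p <- parentIds(tree)[ord]
  pid <- ifelse(is.na(p), -1L, rank[ifelse(is.na(p), 1L, p)])
  fmt <- paste0("%d %d %.", digits, "f %.", digits, "f %.", digits,
                "f %.", digits, "f %d")
  out <- sprintf(fmt, seq_along(ord), nd$region, nd$x, nd$y, nd$z,
                 nd$diameter / 2, pid)
  writeLines(c("# SWC export (morphoforge)", out), path)
  invisible(path)
}
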