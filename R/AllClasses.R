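#' NeuronTree: a rooted directed geometric tree
#'
#' The central container of the package: a neuronal tree represented as a
#' rooted graph with directed edges pointing away from the root.  Each node
#' carries a position (\eqn{\mu m}), a diameter (\eqn{\mu m}) and a
#' small-integer region label following the SWC type convention (1 soma,
#' 3 basal dendrite, 4 apical dendrite; other codes pass through unchanged).
#' Edges connect each node to its direct parent; the root has parent
#' \code{NA}.
#'
#' @slot nodes data.frame with columns \code{x,y,z,diameter,region}.
#' @slot parent integer vector of direct-parent indices, \code{NA} at the root.
#'
#' @param object a \code{NeuronTree}.
#' @name NeuronTree-class
#' @aliases NeuronTree
#' @export
setClass("NeuronTree",
  slots = c(nodes = "data.frame", parent = "integer"))

#' CarrierPointSet: unconnected target points for tree growth
#'
#' Carrier points are the spatial targets that the extended minimum spanning
#' tree algorithm connects one by one into a tree.  The provenance list
#' records the field specification and seed that generated the points.
#'
#' @slot points numeric matrix (n x 3), coordinates in \eqn{\mu m}.
#' @slot provenance list describing how the points were produced.
#' @param object a \code{CarrierPointSet}.
#' @name CarrierPointSet-class
#' @aliases CarrierPointSet
#' @export
setClass("CarrierPointSet",
  slots = c(points = "matrix", provenance = "list"))

#' PassiveParameters: passive membrane properties for electrotonics
#'
#' @slot ra axial resistivity, Ohm cm.
#' @slot rm specific membrane resistivity, Ohm cm^2.
#' @slot i injected current, nA (default 1).
#' @name PassiveParameters-class
#' @aliases PassiveParameters
#' @export
setClass("PassiveParameters",
  slots = c(ra = "numeric", rm = "numeric", i = "numeric"))

#' GrowthParameters: options of the extended minimum spanning tree growth
#'
#' The balancing factor \code{bf} is the single model parameter: the greedy
#' attachment cost is \code{||p-v|| + bf * (PL(v) + ||p-v||)}, i.e. Euclidean
#' wiring cost plus \code{bf} times the resulting path length from the root
#' to the new point.
#'
#' @slot bf balancing factor, dimensionless, >= 0.
#' @slot maxChildren children cap for non-root nodes (multifurcation
#'   suppression; default 2 yields binary trees). \code{Inf} disables the cap.
#' @slot maxChildrenRoot children cap for the root (default \code{Inf}:
#'   somata may emit several stems).
#' @slot cutoff maximum Euclidean attachment distance (default \code{Inf}).
#' @slot extraCostWeight weight of an additional pairwise cost term
#'   (used by image-based reconstruction).
#' @name GrowthParameters-class
#' @aliases GrowthParameters
#' @export
setClass("GrowthParameters",
  slots = c(bf = "numeric", maxChildren = "numeric",
            maxChildrenRoot = "numeric", cutoff = "numeric",
            extraCostWeight = "numeric"))

#' FieldSpec: declarative description of a carrier-point density field
#'
#' A field specification is data, not code: cell classes are described by the
#' geometry of their spanning field and its density profile.  Supported kinds:
#' \code{uniform_disc}, \code{ring_disc}, \code{cone_sphere}, \code{empirical},
#' \code{uniform_box}.
#'
#' @slot kind character, one of the supported field kinds.
#' @slot params named list of geometric/density parameters for the kind.
#' @name FieldSpec-class
#' @aliases FieldSpec
#' @export
setClass("FieldSpec",
  slots = c(kind = "character", params = "list"))

#' ElectrotonicSignature: steady-state node-to-node current transfer
#'
#' The node x node matrix of steady-state potentials (mV): entry (i, j) is
#' the potential at node i when a constant current (default 1 nA) is injected
#' at node j, obtained by inverting the passive conductance matrix.  For a
#' connected passive tree the matrix is symmetric (reciprocity), all entries
#' are positive, and each column attains its maximum on the diagonal.
#'
#' @slot V numeric matrix, mV.
#' @slot parameters the \code{PassiveParameters} used.
#' @param object an \code{ElectrotonicSignature}.
#' @name ElectrotonicSignature-class
#' @aliases ElectrotonicSignature
#' @export
setClass("ElectrotonicSignature",
  slots = c(V = "matrix", parameters = "PassiveParameters"))

#' ImageVolume: a 3D grayscale voxel grid with physical calibration
#'
#' @slot data 3D numeric array of nonnegative intensities.
#' @slot voxelSize numeric length-3, \eqn{\mu m} per voxel along x, y, z.
#' @slot origin numeric length-3, world coordinate (\eqn{\mu m}) of the
#'   corner of voxel (1,1,1).
#' @param object an \code{ImageVolume}.
#' @name ImageVolume-class
#' @aliases ImageVolume
#' @export
setClass("ImageVolume",
  slots = c(data = "array", voxelSize = "numeric", origin = "numeric"))

## ---- validity -------------------------------------------------------------

# Shared diagnostic engine for validateTree and S4 validity.
treeDiagnostics <- function(x, y, z, diameter, parent, warnings = TRUE) {
  out <- character(0)
  n <- length(x)
  if (n < 1L) return("tree has no nodes")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    out <- c(out, "non-finite coordinates")
  if (!is.null(diameter)) {
    if (any(!is.finite(diameter)) || any(diameter < 0))
      out <- c(out, "negative or non-finite diameters")
  }
  roots <- which(is.na(parent))
  if (length(roots) == 0L) out <- c(out, "no root (every node has a parent)")
  if (length(roots) > 1L) out <- c(out, "multiple roots")
  idx <- which(!is.na(parent))
  bad <- idx[parent[idx] < 1L | parent[idx] > n | parent[idx] != floor(parent[idx])]
  if (length(bad)) out <- c(out, "parent references unknown node")
  if (any(parent[idx] == idx, na.rm = TRUE)) out <- c(out, "cycle (node is its own parent)")
  # reachability from the root detects longer cycles / disconnected components
  if (length(roots) == 1L && !length(bad)) {
    reached <- logical(n)
    reached[roots] <- TRUE
    frontier <- roots
    kids <- childrenList(parent)
    while (length(frontier)) {
      nxt <- unlist(kids[frontier], use.names = FALSE)
      nxt <- nxt[!reached[nxt]]
      reached[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(reached)) out <- c(out, "cycle or disconnected nodes (unreachable from root)")
  }
  if (warnings && length(out) == 0L && length(idx)) {
    len <- sqrt((x[idx] - x[parent[idx]])^2 + (y[idx] - y[parent[idx]])^2 +
                  (z[idx] - z[parent[idx]])^2)
    if (any(len == 0)) out <- c(out, "zero-length edge")
  }
  out
}

setValidity("NeuronTree", function(object) {
  nd <- object@nodes
  need <- c("x", "y", "z", "diameter", "region")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  if (nrow(nd) != length(object@parent))
    return("parent length must equal node count")
  d <- treeDiagnostics(nd$x, nd$y, nd$z, nd$diameter, object@parent,
                       warnings = FALSE)
  if (length(d)) d else TRUE
})

setValidity("PassiveParameters", function(object) {
  if (object@ra <= 0 || object@rm <= 0 || object@i <= 0)
    "ra, rm and i must all be positive" else TRUE
})

setValidity("GrowthParameters", function(object) {
  if (object@bf < 0) return("bf must be >= 0")
  if (object@maxChildren < 1) return("maxChildren must be >= 1")
  TRUE
})

setValidity("CarrierPointSet", function(object) {
  p <- object@points
  if (ncol(p) != 3L) return("points must be an n x 3 matrix")
  if (nrow(p) && !all(is.finite(p))) return("non-finite carrier coordinates")
  TRUE
})

setValidity("ImageVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be three positive values")
  if (!all(is.finite(object@data))) return("non-finite intensities")
  TRUE
})

setValidity("ElectrotonicSignature", function(object) {
  if (nrow(object@V) != ncol(object@V)) return("V must be square")
  TRUE
})

## ---- constructors ---------------------------------------------------------

#' Construct a NeuronTree
#'
#' @param x,y,z numeric node coordinates in \eqn{\mu m}.
#' @param diameter node diameters in \eqn{\mu m} (recycled; default 1, the
#'   convention for freshly grown trees before diameter tapering).
#' @param region integer region labels (SWC type codes; recycled; default 3).
#' @param parent integer parent index per node, \code{NA} at the root.
#' @param validate check tree invariants (default TRUE).
#' @return a \code{NeuronTree}.
#' @examples
#' tr <- neuronTree(x = c(0, 10, 20), y = c(0, 0, 0), z = c(0, 0, 0),
#'                  parent = c(NA, 1, 2))
#' totalCableLength(tr)
#' @rdname NeuronTree-class
#' @export
neuronTree <- function(x, y, z = 0, diameter = 1, region = 3L, parent,
                       validate = TRUE) {
  n <- length(x)
  nodes <- data.frame(
    x = as.numeric(x), y = as.numeric(y),
    z = rep_len(as.numeric(z), n),
    diameter = rep_len(as.numeric(diameter), n),
    region = rep_len(as.integer(region), n))
  obj <- new("NeuronTree", nodes = nodes, parent = as.integer(parent))
  if (validate) validObject(obj)
  obj
}

#' Construct passive membrane parameters
#'
#' Defaults are the passive set used for insect dendrites
#' (\code{ra} = 100 Ohm cm, \code{rm} = 2000 Ohm cm^2); cortical pyramidal
#' cells are typically modelled with \code{rm} = 20000 Ohm cm^2.
#'
#' @param ra axial resistivity, Ohm cm.
#' @param rm membrane resistivity, Ohm cm^2.
#' @param i injected current, nA.
#' @return a \code{PassiveParameters}.
#' @rdname PassiveParameters-class
#' @export
passiveParameters <- function(ra = 100, rm = 2000, i = 1) {
  obj <- new("PassiveParameters", ra = ra, rm = rm, i = i)
  validObject(obj)
  obj
}

#' Construct growth parameters
#'
#' @param bf balancing factor (>= 0).
#' @param suppressMultifurcations cap non-root nodes at \code{maxChildren}
#'   children (default TRUE).
#' @param maxChildren children cap when suppression is on (default 2).
#' @param maxChildrenRoot children cap at the root (default \code{Inf}).
#' @param cutoff maximum attachment distance in \eqn{\mu m} (default \code{Inf}:
#'   all carriers are connected).
#' @param extraCostWeight weight for an additional pairwise cost matrix
#'   (default 1; only used when such a matrix is supplied).
#' @return a \code{GrowthParameters}.
#' @rdname GrowthParameters-class
#' @export
growthParameters <- function(bf = 0, suppressMultifurcations = TRUE,
                             maxChildren = 2, maxChildrenRoot = Inf,
                             cutoff = Inf, extraCostWeight = 1) {
  obj <- new("GrowthParameters", bf = bf,
             maxChildren = if (suppressMultifurcations) maxChildren else Inf,
             maxChildrenRoot = maxChildrenRoot, cutoff = cutoff,
             extraCostWeight = extraCostWeight)
  validObject(obj)
  obj
}

#' Construct a carrier point set from raw coordinates
#'
#' @param points numeric matrix (n x 2 or n x 3); 2D points get z = 0.
#' @param provenance optional list recording origin of the points.
#' @return a \code{CarrierPointSet}.
#' @rdname CarrierPointSet-class
#' @export
carrierPointSet <- function(points, provenance = list()) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0, 3)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  colnames(points) <- c("x", "y", "z")
  obj <- new("CarrierPointSet", points = points, provenance = provenance)
  validObject(obj)
  obj
}

#' Construct an image volume
#'
#' @param data 3D numeric array of intensities (x, y, z index order).
#' @param voxelSize \eqn{\mu m} per voxel, scalar or length 3.
#' @param origin world coordinate of the corner of the first voxel.
#' @return an \code{ImageVolume}.
#' @rdname ImageVolume-class
#' @export
imageVolume <- function(data, voxelSize = 1, origin = c(0, 0, 0)) {
  obj <- new("ImageVolume", data = data,
             voxelSize = rep_len(as.numeric(voxelSize), 3L),
             origin = rep_len(as.numeric(origin), 3L))
  validObject(obj)
  obj
}

## ---- accessors ------------------------------------------------------------

#' @rdname NeuronTree-class
#' @export
setMethod("nNodes", "NeuronTree", function(object) nrow(object@nodes))

#' @rdname NeuronTree-class
#' @export
setMethod("xyz", "NeuronTree", function(object)
  cbind(x = object@nodes$x, y = object@nodes$y, z = object@nodes$z))

#' @rdname NeuronTree-class
#' @export
setMethod("diameters", "NeuronTree", function(object) object@nodes$diameter)

#' @rdname NeuronTree-class
#' @export
setMethod("regions", "NeuronTree", function(object) object@nodes$region)

#' @rdname NeuronTree-class
#' @export
setMethod("parentIds", "NeuronTree", function(object) object@parent)

#' @rdname NeuronTree-class
#' @export
setMethod("rootIndex", "NeuronTree", function(object)
  which(is.na(object@parent)))

#' @rdname CarrierPointSet-class
#' @export
setMethod("carrierPoints", "CarrierPointSet", function(object) object@points)

#' @rdname CarrierPointSet-class
#' @export
setMethod("nNodes", "CarrierPointSet", function(object) nrow(object@points))

#' @rdname ImageVolume-class
#' @export
setMethod("voxelData", "ImageVolume", function(object) object@data)

#' @rdname ImageVolume-class
#' @export
setMethod("voxelSize", "ImageVolume", function(object) object@voxelSize)

#' @rdname ElectrotonicSignature-class
#' @export
setMethod("potentials", "ElectrotonicSignature", function(object) object@V)

## ---- show methods ---------------------------------------------------------

setMethod("show", "NeuronTree", function(object) {
  cls <- classifyNodes(object)
  cat(sprintf("NeuronTree with %d nodes (%d branch points, %d terminals)\n",
              nNodes(object), sum(cls == "branch"), sum(cls == "termination")))
  cat(sprintf("  total cable length: %.2f um\n", totalCableLength(object)))
  invisible(object)
})

setMethod("show", "CarrierPointSet", function(object) {
  cat(sprintf("CarrierPointSet with %d points", nrow(object@points)))
  if (!is.null(object@provenance$kind))
    cat(sprintf(" (%s field)", object@provenance$kind))
  cat("\n")
  invisible(object)
})

setMethod("show", "ElectrotonicSignature", function(object) {
  cat(sprintf("ElectrotonicSignature: %d x %d potentials (mV), range %.3g..%.3g\n",
              nrow(object@V), ncol(object@V), min(object@V), max(object@V)))
  invisible(object)
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %d x %d x %d voxels, voxel size %g x %g x %g um\n",
              d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3]))
  invisible(object)
})

setMethod("show", "GrowthParameters", function(object) {
  cat(sprintf("GrowthParameters: bf = %g, maxChildren = %g, root cap = %g\n",
              object@bf, object@maxChildren, object@maxChildrenRoot))
  invisible(object)
})

setMethod("show", "FieldSpec", function(object) {
  cat(sprintf("FieldSpec of kind '%s'\n", object@kind))
  invisible(object)
})
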