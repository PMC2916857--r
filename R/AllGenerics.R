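#' @rdname NeuronTree-class
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))

#' @rdname NeuronTree-class
#' @export
setGeneric("xyz", function(object) standardGeneric("xyz"))

#' @rdname NeuronTree-class
#' @export
setGeneric("diameters", function(object) standardGeneric("diameters"))

#' @rdname NeuronTree-class
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))

#' @rdname NeuronTree-class
#' @export
setGeneric("parentIds", function(object) standardGeneric("parentIds"))

#' @rdname NeuronTree-class
#' @export
setGeneric("rootIndex", function(object) standardGeneric("rootIndex"))

#' Validate a rooted tree structure
#'
#' Returns a character vector of invariant violations (empty when valid):
#' multiple or missing roots, parents referencing unknown nodes, cycles,
#' non-finite coordinates, negative diameters.  Zero-length edges are
#' permitted (they occur in real reconstructions) but reported as
#' \code{"zero-length edge"} notes; equidistant resampling removes them.
#'
#' @param object a \code{NeuronTree}, or a \code{data.frame} with columns
#'   \code{x,y,z,parent} (and optionally \code{diameter}) where \code{parent}
#'   is \code{NA} for the root.
#' @param ... unused.
#' @return character vector of diagnostics; \code{character(0)} for a valid tree.
#' @export
setGeneric("validateTree", function(object, ...) standardGeneric("validateTree"))

#' @rdname CarrierPointSet-class
#' @export
setGeneric("carrierPoints", function(object) standardGeneric("carrierPoints"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname ImageVolume-class
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname ElectrotonicSignature-class
#' @export
setGeneric("potentials", function(object) standardGeneric("potentials"))
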