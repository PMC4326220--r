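#' Accessors for mimoprune objects
#'
#' Slot access goes through these accessors rather than \code{@}.
#'
#' @param x a mimoprune S4 object
#' @return \code{surfaceResidues}: residue keys of the evaluation universe;
#'   \code{epitopeResidues}: annotated epitope keys;
#'   \code{residueTable}: the per-residue data.frame;
#'   \code{predictedResidues}: predicted epitope keys;
#'   \code{keptResidues}/\code{removedResidues}: the ensemble's partition;
#'   \code{patchMembers}: member keys of a patch graph.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("surfaceResidues", function(x) standardGeneric("surfaceResidues"))
#' @rdname accessors
#' @export
setMethod("surfaceResidues", "SurfaceSet", function(x) x@residues)

#' @rdname accessors
#' @export
setGeneric("epitopeResidues", function(x) standardGeneric("epitopeResidues"))
#' @rdname accessors
#' @export
setMethod("epitopeResidues", "SurfaceSet", function(x) x@epitope)

#' @rdname accessors
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))
#' @rdname accessors
#' @export
setMethod("residueTable", "SurfaceSet", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("residueTable", "AntigenStructure", function(x) x@residues)

#' @rdname accessors
#' @export
setGeneric("predictedResidues", function(x) standardGeneric("predictedResidues"))
#' @rdname accessors
#' @export
setMethod("predictedResidues", "EpitopePrediction", function(x) x@predicted)

#' @rdname accessors
#' @export
setGeneric("keptResidues", function(x) standardGeneric("keptResidues"))
#' @rdname accessors
#' @export
setMethod("keptResidues", "PrunedSurface", function(x) x@kept)

#' @rdname accessors
#' @export
setGeneric("removedResidues", function(x) standardGeneric("removedResidues"))
#' @rdname accessors
#' @export
setMethod("removedResidues", "PrunedSurface", function(x) x@removed)

#' @rdname accessors
#' @export
setGeneric("patchMembers", function(x) standardGeneric("patchMembers"))
#' @rdname accessors
#' @export
setMethod("patchMembers", "PatchGraph", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("patchEdges", function(x) standardGeneric("patchEdges"))
#' @rdname accessors
#' @export
setMethod("patchEdges", "PatchGraph", function(x) {
  if (nrow(x@edges) == 0)
    return(data.frame(u = character(0), v = character(0)))
  data.frame(u = x@members[x@edges[, 1]], v = x@members[x@edges[, 2]])
})
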