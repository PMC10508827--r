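#' @rdname Image3D-accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname Image3D-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname Image3D-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname Image3D-accessors
#' @export
setGeneric("imgDim", function(x) standardGeneric("imgDim"))

#' @rdname TetMesh-accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname TetMesh-accessors
#' @export
setGeneric("tets", function(x) standardGeneric("tets"))

#' @rdname TetMesh-accessors
#' @export
setGeneric("tetLabels", function(x) standardGeneric("tetLabels"))

#' @rdname TetMesh-accessors
#' @export
setGeneric("tetVolumes", function(x) standardGeneric("tetVolumes"))

#' @rdname MatchSet-accessors
#' @export
setGeneric("matchPoints", function(x) standardGeneric("matchPoints"))

#' @rdname MatchSet-accessors
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))

#' @rdname MatchSet-accessors
#' @export
setGeneric("confidences", function(x) standardGeneric("confidences"))

#' @rdname MatchSet-accessors
#' @export
setGeneric("matchWeights", function(x) standardGeneric("matchWeights"))

#' @rdname fieldValues
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
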