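#' @rdname HaploAlignment-class
#' @param x an object
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname HaploAlignment-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname HaplotypeTable-class
#' @param x an object
#' @export
setGeneric("hapCounts", function(x) standardGeneric("hapCounts"))

#' @rdname HaplotypeTable-class
#' @export
setGeneric("hapSequences", function(x) standardGeneric("hapSequences"))

#' @rdname HaplotypeTable-class
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypeTable-class
#' @export
setGeneric("nPolymorphic", function(x) standardGeneric("nPolymorphic"))

#' @rdname HaplotypeTable-class
#' @export
setGeneric("areaMap", function(x) standardGeneric("areaMap"))

#' @rdname HaploNetwork-class
#' @param x an object
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname HaploNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
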