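#' @rdname TriangleMesh-accessors
#' @export
setGeneric("meshId", function(x) standardGeneric("meshId"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("side", function(x) standardGeneric("side"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriangleMesh-accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname applyTransform
#' @export
setGeneric("applyTransform", function(x, transform)
  standardGeneric("applyTransform"))

#' Root-mean-square of a set of distances
#'
#' `sqrt(mean(d^2))` over the unsigned distances: the similarity proxy used
#' throughout. Squaring makes the summary insensitive to sign, so receding
#' and prominent areas do not cancel as they would in an arithmetic mean.
#'
#' @param x a [DistanceField-class] or a numeric vector of distances (mm).
#' @return RMS distance in mm.
#' @examples
#' rms(c(3, 4))  # sqrt(12.5)
#' @export
setGeneric("rms", function(x) standardGeneric("rms"))
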