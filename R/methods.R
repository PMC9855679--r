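#' Accessors for TriangleMesh and LandmarkSet
#'
#' @param x a [TriangleMesh-class] or [LandmarkSet-class].
#' @return `meshId`, `side`: character scalars. `vertices`: numeric `n x 3`
#'   matrix (mm). `faces`: integer `m x 3` matrix of 1-based indices.
#'   `nVertices`, `nFaces`: integers. `landmarkPoints`: named `3 x 3` matrix.
#' @name TriangleMesh-accessors
NULL

#' @rdname TriangleMesh-accessors
setMethod("meshId", "TriangleMesh", function(x) x@id)
#' @rdname TriangleMesh-accessors
setMethod("vertices", "TriangleMesh", function(x) x@vertices)
#' @rdname TriangleMesh-accessors
setMethod("faces", "TriangleMesh", function(x) x@faces)
#' @rdname TriangleMesh-accessors
setMethod("side", "TriangleMesh", function(x) x@side)
#' @rdname TriangleMesh-accessors
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
#' @rdname TriangleMesh-accessors
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))
#' @rdname TriangleMesh-accessors
setMethod("meshId", "LandmarkSet", function(x) x@meshId)

#' @rdname TriangleMesh-accessors
#' @export
landmarkPoints <- function(x) x@points

#' Accessors for RigidTransform
#'
#' @param x a [RigidTransform-class].
#' @return `rotation`: `3 x 3` matrix; `translation`: length-3 vector (mm).
#' @name RigidTransform-accessors
#' @export
rotation <- function(x) x@rotation

#' @rdname RigidTransform-accessors
#' @export
translation <- function(x) x@translation

#' Accessors for DistanceField
#'
#' @param x a [DistanceField-class].
#' @return numeric vectors of per-vertex distances (mm).
#' @name DistanceField-accessors
#' @export
distances <- function(x) x@distances

#' @rdname DistanceField-accessors
#' @export
signedDistances <- function(x) x@signedDistances

#' @describeIn rms RMS of the unsigned per-vertex distances.
setMethod("rms", "DistanceField", function(x) sqrt(mean(x@distances^2)))

#' @describeIn rms RMS of a plain numeric vector.
setMethod("rms", "numeric", function(x) {
  if (length(x) == 0L) stop("rms of an empty vector is undefined")
  if (any(!is.finite(x))) stop("distances must be finite")
  sqrt(mean(x^2))
})

#' Apply a rigid transform
#'
#' Maps `x -> R x + t`. For meshes and landmark sets every point is mapped;
#' topology, ids and sides are unchanged.
#'
#' @param x an `n x 3` matrix of points, a [TriangleMesh-class] or a
#'   [LandmarkSet-class].
#' @param transform a [RigidTransform-class].
#' @return An object of the same class as `x`.
#' @name applyTransform
NULL

#' @rdname applyTransform
setMethod("applyTransform", "matrix", function(x, transform) {
  x %*% t(transform@rotation) +
    matrix(transform@translation, nrow(x), 3, byrow = TRUE)
})

#' @rdname applyTransform
setMethod("applyTransform", "TriangleMesh", function(x, transform) {
  x@vertices <- applyTransform(x@vertices, transform)
  validObject(x)
  x
})

#' @rdname applyTransform
setMethod("applyTransform", "LandmarkSet", function(x, transform) {
  nm <- rownames(x@points)
  x@points <- applyTransform(x@points, transform)
  rownames(x@points) <- nm
  validObject(x)
  x
})

#' Compose two rigid transforms
#'
#' `composeTransforms(a, b)` is the transform that applies `b` first, then
#' `a` (like matrix multiplication `a %*% b`).
#'
#' @param a,b [RigidTransform-class] objects.
#' @return A [RigidTransform-class].
#' @export
composeTransforms <- function(a, b) {
  RigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#'
#' @param x a [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(x) {
  Rt <- t(x@rotation)
  RigidTransform(Rt, as.numeric(-Rt %*% x@translation))
}

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh '%s' (%s): %d vertices, %d faces\n",
              object@id, object@side, nrow(object@vertices),
              nrow(object@faces)))
  bb <- apply(object@vertices, 2, range)
  cat(sprintf("  bounding box [mm]: x %.2f..%.2f, y %.2f..%.2f, z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet for mesh '%s':\n", object@meshId))
  print(round(object@points, 4))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang * 180 / pi, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult: %d iterations (%s), final RMS %.6g mm\n",
              object@iterations,
              if (object@converged) "converged" else "NOT converged",
              object@finalRMS))
})

setMethod("show", "DistanceField", function(object) {
  cat(sprintf("DistanceField %s -> %s: %d vertices, RMS %.4f mm, mean |d| %.4f mm\n",
              object@sourceId, object@targetId, length(object@distances),
              sqrt(mean(object@distances^2)), mean(object@distances)))
})

setMethod("show", "ComparisonMatrix", function(object) {
  n <- sum(!is.na(object@rms))
  cat(sprintf("ComparisonMatrix [%s]: %d left x %d right, %d cells (%d matches, %d mismatches)\n",
              object@group, length(object@leftIds), length(object@rightIds),
              n, nrow(object@truth), n - nrow(object@truth)))
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport at %.4g mm: tp=%d fp=%d tn=%d fn=%d | sensitivity %.1f%%, specificity %.1f%%\n",
              object@thresholdMM, object@tp, object@fp, object@tn, object@fn,
              round(object@sensitivity, 1), round(object@specificity, 1)))
})

setMethod("show", "RepeatabilityReport", function(object) {
  cat(sprintf("RepeatabilityReport (%s-observer, n=%d): TEM %.4f mm, rTEM %.2f%%\n",
              object@mode, object@nPairs, object@temMM, object@rtemPercent))
})
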