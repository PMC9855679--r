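#' @useDynLib OsteoPair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.LANDMARK_NAMES <- c("sym_sup", "sym_inf", "obt_med")

#' TriangleMesh: a bone surface model
#'
#' Triangulated surface in millimetres: an `n x 3` vertex matrix and an
#' `m x 3` matrix of 1-based vertex indices. The `side` flag records the
#' anatomical side (`"left"`, `"right"` or `"unknown"`); `meta` carries
#' optional per-vertex scalars (e.g. the `quality` channel of a distance-map
#' PLY).
#'
#' @slot id character label identifying the mesh.
#' @slot vertices numeric `n x 3` matrix of coordinates (mm).
#' @slot faces integer `m x 3` matrix of vertex indices (1-based).
#' @slot side one of `"left"`, `"right"`, `"unknown"`.
#' @slot meta list of optional annotations.
#' @exportClass TriangleMesh
setClass("TriangleMesh",
  slots = c(id = "character", vertices = "matrix", faces = "matrix",
            side = "character", meta = "list"))

setValidity("TriangleMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  if (!is.numeric(v) || ncol(v) != 3L)
    return("vertices must be a numeric matrix with 3 columns")
  if (!all(is.finite(v)))
    return("vertex coordinates must all be finite")
  if (nrow(v) < 3L)
    return("a mesh needs at least 3 vertices")
  if (ncol(f) != 3L || nrow(f) < 1L)
    return("faces must be an m x 3 matrix with m >= 1")
  if (any(f != round(f)))
    return("face indices must be integers")
  if (min(f) < 1L || max(f) > nrow(v))
    return(sprintf("face index out of range [1, %d]", nrow(v)))
  if (length(object@side) != 1L ||
      !object@side %in% c("left", "right", "unknown"))
    return("side must be one of 'left', 'right', 'unknown'")
  TRUE
})

#' Construct a TriangleMesh
#'
#' @param vertices numeric `n x 3` matrix (mm).
#' @param faces `m x 3` matrix of 1-based vertex indices.
#' @param id mesh label.
#' @param side `"left"`, `"right"` or `"unknown"`.
#' @param meta optional annotation list.
#' @return A validated [TriangleMesh-class] object.
#' @examples
#' m <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   matrix(c(1L, 2L, 3L), 1))
#' nFaces(m)
#' @export
TriangleMesh <- function(vertices, faces, id = "mesh", side = "unknown",
                         meta = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("TriangleMesh", id = id, vertices = vertices, faces = faces,
      side = side, meta = meta)
}

#' LandmarkSet: three named anatomical points
#'
#' Seeds the coarse alignment. The three landmarks are the most superior and
#' most inferior points of the pubic symphysis (`sym_sup`, `sym_inf`) and the
#' most medial point of the obturator foramen (`obt_med`). They must be
#' non-collinear (pairwise distances > 1e-6 mm, triangle area > 1e-9 mm^2).
#'
#' @slot meshId id of the mesh the landmarks annotate.
#' @slot points numeric `3 x 3` matrix, rows named
#'   `sym_sup`, `sym_inf`, `obt_med` (mm).
#' @exportClass LandmarkSet
setClass("LandmarkSet", slots = c(meshId = "character", points = "matrix"))

setValidity("LandmarkSet", function(object) {
  p <- object@points
  if (!is.numeric(p) || nrow(p) != 3L || ncol(p) != 3L)
    return("points must be a 3 x 3 numeric matrix")
  if (is.null(rownames(p)) || !setequal(rownames(p), .LANDMARK_NAMES) ||
      anyDuplicated(rownames(p)))
    return(sprintf("landmarks must be named exactly {%s}",
                   paste(.LANDMARK_NAMES, collapse = ", ")))
  if (!all(is.finite(p)))
    return("landmark coordinates must be finite")
  d12 <- sqrt(sum((p[1, ] - p[2, ])^2))
  d13 <- sqrt(sum((p[1, ] - p[3, ])^2))
  d23 <- sqrt(sum((p[2, ] - p[3, ])^2))
  if (min(d12, d13, d23) <= 1e-6)
    return("landmarks are degenerate: pairwise distance <= 1e-6 mm")
  cr <- crossprod3(p[2, ] - p[1, ], p[3, ] - p[1, ])
  if (0.5 * sqrt(sum(cr^2)) <= 1e-9)
    return("landmarks are collinear: triangle area <= 1e-9 mm^2")
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param meshId id of the annotated mesh.
#' @param points `3 x 3` matrix with rownames `sym_sup`, `sym_inf`,
#'   `obt_med`, or a named list of 3-vectors.
#' @return A validated [LandmarkSet-class].
#' @examples
#' LandmarkSet("a", list(sym_sup = c(0, 10, 0), sym_inf = c(0, -10, 0),
#'                       obt_med = c(15, 0, 2)))
#' @export
LandmarkSet <- function(meshId, points) {
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  missing <- setdiff(.LANDMARK_NAMES, rownames(points))
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  points <- points[.LANDMARK_NAMES, , drop = FALSE]
  new("LandmarkSet", meshId = as.character(meshId), points = points)
}

#' RigidTransform: proper rigid motion (rotation + translation)
#'
#' The registration output: `x -> R x + t` with `R` orthonormal and
#' `det(R) = +1` (no reflection, no scale — only shape is compared, never
#' size).
#'
#' @slot rotation `3 x 3` proper rotation matrix.
#' @slot translation length-3 numeric vector (mm).
#' @exportClass RigidTransform
setClass("RigidTransform",
  slots = c(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!is.numeric(R) || any(dim(R) != c(3L, 3L)))
    return("rotation must be a 3 x 3 numeric matrix")
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    return("translation must be a finite length-3 vector")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation is not orthonormal (tolerance 1e-9)")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must be proper: det = +1 (no reflection, no scale)")
  TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation `3 x 3` proper rotation matrix (default identity).
#' @param translation length-3 vector in mm (default zero).
#' @return A validated [RigidTransform-class].
#' @examples
#' identityTransform()
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  storage.mode(rotation) <- "double"
  dimnames(rotation) <- NULL
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' @rdname RigidTransform
#' @export
identityTransform <- function() RigidTransform()

#' RegistrationResult: outcome of an ICP refinement
#'
#' @slot transform the fitted [RigidTransform-class] (absolute: maps the
#'   original moving vertices onto the fixed surface).
#' @slot iterations number of ICP iterations executed.
#' @slot converged logical; `FALSE` means the iteration cap was hit before
#'   the RMS change fell below tolerance (the result is still returned).
#' @slot finalRMS RMS point-to-surface distance (mm) at the final transform.
#' @slot rmsTrajectory per-iteration RMS (mm), non-increasing.
#' @exportClass RegistrationResult
setClass("RegistrationResult",
  slots = c(transform = "RigidTransform", iterations = "integer",
            converged = "logical", finalRMS = "numeric",
            rmsTrajectory = "numeric"))

setValidity("RegistrationResult", function(object) {
  tr <- object@rmsTrajectory
  if (length(tr) && any(diff(tr) > 1e-8))
    return("rmsTrajectory must be non-increasing")
  if (length(object@finalRMS) != 1L || object@finalRMS < 0)
    return("finalRMS must be a single non-negative value")
  TRUE
})

#' DistanceField: per-vertex distances from one surface to another
#'
#' Distances from each vertex of the (registered) source mesh to its closest
#' point on the target surface. The signed value is positive where the
#' source lies outside the target along the interpolated target normal
#' (prominent areas) and negative where it recedes behind it; `|signed|`
#' always equals the unsigned distance.
#'
#' @slot sourceId id of the source (moving, registered) mesh.
#' @slot targetId id of the target (fixed) mesh.
#' @slot distances unsigned per-vertex distances (mm).
#' @slot signedDistances signed per-vertex distances (mm).
#' @exportClass DistanceField
setClass("DistanceField",
  slots = c(sourceId = "character", targetId = "character",
            distances = "numeric", signedDistances = "numeric"))

setValidity("DistanceField", function(object) {
  d <- object@distances
  s <- object@signedDistances
  if (length(d) == 0L) return("empty distance field")
  if (length(d) != length(s))
    return("distances and signedDistances must have equal length")
  if (any(d < 0)) return("unsigned distances must be >= 0")
  if (max(abs(abs(s) - d)) > 1e-9)
    return("|signedDistances| must equal distances (tolerance 1e-9)")
  TRUE
})

#' ComparisonMatrix: all-against-all RMS values with ground truth
#'
#' Grid of superimposition RMS values, left models on rows and right models
#' on columns. Cells never compared (e.g. cross-sex combinations in a pooled
#' design) are `NA`; counts and classification run over the non-`NA` cells.
#' `truth` lists the (left, right) pairs known to come from the same
#' individual; each id may appear in at most one truth pair.
#'
#' @slot leftIds,rightIds ordered model labels.
#' @slot rms numeric `length(leftIds) x length(rightIds)` matrix (mm).
#' @slot truth two-column character matrix of true pairs (`left`, `right`).
#' @slot group label, e.g. `"males"`, `"females"` or `"combined"`.
#' @exportClass ComparisonMatrix
setClass("ComparisonMatrix",
  slots = c(leftIds = "character", rightIds = "character", rms = "matrix",
            truth = "matrix", group = "character"))

setValidity("ComparisonMatrix", function(object) {
  m <- object@rms
  if (nrow(m) != length(object@leftIds) || ncol(m) != length(object@rightIds))
    return("rms dimensions do not match id vectors")
  vals <- m[!is.na(m)]
  if (length(vals) == 0L) return("comparison matrix has no cells")
  if (any(!is.finite(vals)) || any(vals <= 0))
    return("all RMS values must be finite and > 0")
  tr <- object@truth
  if (ncol(tr) != 2L) return("truth must have two columns (left, right)")
  if (nrow(tr)) {
    if (anyDuplicated(tr[, 1L]) || anyDuplicated(tr[, 2L]))
      return("each id may appear in at most one truth pair")
    if (!all(tr[, 1L] %in% object@leftIds) ||
        !all(tr[, 2L] %in% object@rightIds))
      return("truth pair references an unknown id")
    for (i in seq_len(nrow(tr)))
      if (is.na(m[match(tr[i, 1L], object@leftIds),
                  match(tr[i, 2L], object@rightIds)]))
        return(sprintf("truth pair (%s, %s) has no RMS cell",
                       tr[i, 1L], tr[i, 2L]))
  }
  TRUE
})

#' ClassificationReport: confusion counts and rates at one threshold
#'
#' @slot thresholdMM RMS cut-off (mm); a cell is called a match iff its RMS
#'   is less than or equal to the threshold (inclusive rule).
#' @slot tp,fp,tn,fn confusion counts.
#' @slot sensitivity,specificity percentages (raw, unrounded).
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  slots = c(thresholdMM = "numeric", tp = "integer", fp = "integer",
            tn = "integer", fn = "integer", sensitivity = "numeric",
            specificity = "numeric"))

setValidity("ClassificationReport", function(object) {
  cts <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(cts < 0)) return("confusion counts must be >= 0")
  if (object@tp + object@fn > 0 && !is.na(object@sensitivity) &&
      abs(object@sensitivity - 100 * object@tp / (object@tp + object@fn)) > 1e-9)
    return("sensitivity inconsistent with counts")
  if (object@tn + object@fp > 0 && !is.na(object@specificity) &&
      abs(object@specificity - 100 * object@tn / (object@tn + object@fp)) > 1e-9)
    return("specificity inconsistent with counts")
  TRUE
})

#' RepeatabilityReport: technical error of measurement
#'
#' @slot temMM absolute technical error of measurement (mm).
#' @slot rtemPercent TEM as a percentage of the grand mean.
#' @slot nPairs number of repeated measurement pairs.
#' @slot mode `"intra"` or `"inter"` observer.
#' @exportClass RepeatabilityReport
setClass("RepeatabilityReport",
  slots = c(temMM = "numeric", rtemPercent = "numeric", nPairs = "integer",
            mode = "character"))

setValidity("RepeatabilityReport", function(object) {
  if (object@temMM < 0 || object@rtemPercent < 0)
    return("TEM and rTEM must be >= 0")
  TRUE
})
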