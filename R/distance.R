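#' Per-vertex point-to-surface distances
#'
#' For each vertex of the (already registered) source mesh, the Euclidean
#' distance to its closest point on the target triangulated surface
#' (point-to-triangle projection, not nearest vertex, so the result is
#' independent of the target's sampling density; a `"vertex"` mode is
#' available for comparison). No transform is applied here — register
#' first, then measure.
#'
#' The sign comes from the dot product of the offset vector with the
#' target's angle/area-weighted vertex normals barycentrically interpolated
#' at the closest point: positive where the source is prominent (outside
#' the target surface), negative where it recedes behind it.
#'
#' @param source registered moving [TriangleMesh-class].
#' @param target fixed [TriangleMesh-class].
#' @param mode `"surface"` (default) or `"vertex"`.
#' @return A [DistanceField-class] with one entry per source vertex.
#' @seealso [rms()], [writeDistanceMap()]
#' @export
surfaceDistances <- function(source, target, mode = c("surface", "vertex")) {
  validObject(source)
  validObject(target)
  mode <- match.arg(mode)
  P <- source@vertices
  if (mode == "vertex") {
    tv <- target@vertices
    idx <- vapply(seq_len(nrow(P)), function(i) {
      which.min(colSums((t(tv) - P[i, ])^2))
    }, integer(1))
    cp <- tv[idx, , drop = FALSE]
    d <- sqrt(rowSums((P - cp)^2))
    nrm <- vertexNormals(target)[idx, , drop = FALSE]
  } else {
    res <- cpp_closest_on_surface(P, target@vertices, target@faces)
    cp <- res$points
    d <- res$dist
    vn <- vertexNormals(target)
    f <- target@faces[res$face, , drop = FALSE]
    nrm <- res$bary[, 1] * vn[f[, 1], , drop = FALSE] +
           res$bary[, 2] * vn[f[, 2], , drop = FALSE] +
           res$bary[, 3] * vn[f[, 3], , drop = FALSE]
  }
  sgn <- sign(rowSums((P - cp) * nrm))
  sgn[sgn == 0 | d == 0] <- 1
  signed <- sgn * d
  signed[d == 0] <- 0
  new("DistanceField", sourceId = source@id, targetId = target@id,
      distances = d, signedDistances = signed)
}

# diverging blue -> green -> red map on [-1, 1]
.divergingRGB <- function(t) {
  t <- pmax(-1, pmin(1, t))
  r <- ifelse(t > 0, 255 * t, 0)
  g <- 255 * (1 - abs(t))
  b <- ifelse(t < 0, -255 * t, 0)
  cbind(round(r), round(g), round(b))
}

#' Write a chromatic distance map as PLY
#'
#' Exports the source mesh with a per-vertex `quality` scalar holding the
#' signed distance and RGB from a diverging colormap: blue for receding
#' areas (negative), green where the surfaces coincide, through yellow and
#' orange to red for prominent areas (positive), clipped at
#' `± colorRange` mm. Re-reading the file with [readMesh()] recovers the
#' signed distances in `meta$quality`.
#'
#' @param source the registered moving [TriangleMesh-class].
#' @param field matching [DistanceField-class].
#' @param path output `.ply` path.
#' @param colorRange clip range in mm (default 2.0, covering the observed
#'   match/mismatch RMS range).
#' @return Invisibly, `path`.
#' @export
writeDistanceMap <- function(source, field, path, colorRange = 2.0) {
  validObject(source)
  validObject(field)
  if (length(field@signedDistances) != nrow(source@vertices))
    stop("distance field length does not match source vertex count")
  if (colorRange <= 0) stop("colorRange must be > 0")
  rgb <- .divergingRGB(field@signedDistances / colorRange)
  .writePLY(source, path, quality = field@signedDistances, rgb = rgb)
  invisible(path)
}

#' Export per-vertex distances as CSV
#'
#' @param field a [DistanceField-class].
#' @param path output CSV path (columns `vertex_index`, `d_signed_mm`).
#' @return Invisibly, `path`.
#' @export
writeDistancesCSV <- function(field, path) {
  validObject(field)
  utils::write.csv(data.frame(vertex_index = seq_along(field@signedDistances),
                              d_signed_mm = field@signedDistances),
                   path, row.names = FALSE)
  invisible(path)
}
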