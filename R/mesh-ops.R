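#' Mirror a mesh across a coordinate plane
#'
#' Reflects the vertices across the chosen plane and reverses the face
#' winding so that outward orientation is preserved (a reflection alone
#' turns the surface inside out). The `side` flag is flipped left/right.
#' The choice of plane is immaterial for pair-matching: the subsequent
#' rigid registration absorbs any rigid difference between mirror planes.
#'
#' @param mesh a [TriangleMesh-class].
#' @param plane `"x"`, `"y"` or `"z"` — the coordinate set to zero on the
#'   mirror plane (default `x = 0`).
#' @return The mirrored [TriangleMesh-class].
#' @examples
#' s <- sphereMesh(5, 1)
#' m <- mirrorMesh(mirrorMesh(s))
#' all.equal(vertices(m), vertices(s))
#' @export
mirrorMesh <- function(mesh, plane = c("x", "y", "z")) {
  validObject(mesh)
  plane <- match.arg(plane)
  ax <- match(plane, c("x", "y", "z"))
  v <- mesh@vertices
  v[, ax] <- -v[, ax]
  mesh@vertices <- v
  mesh@faces <- mesh@faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh@side <- switch(mesh@side, left = "right", right = "left", "unknown")
  mesh
}

#' Mirror a landmark set across a coordinate plane
#'
#' Companion to [mirrorMesh()]: landmark names are anatomical (not
#' side-specific), so only coordinates change.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param plane `"x"`, `"y"` or `"z"`.
#' @return The mirrored [LandmarkSet-class].
#' @export
mirrorLandmarks <- function(landmarks, plane = c("x", "y", "z")) {
  validObject(landmarks)
  plane <- match.arg(plane)
  ax <- match(plane, c("x", "y", "z"))
  landmarks@points[, ax] <- -landmarks@points[, ax]
  landmarks
}

#' Remove interior geometry by external-viewpoint visibility
#'
#' Segmented bone models retain trabecular (spongious) remnants inside the
#' cortical shell that would corrupt surface registration. This operation
#' keeps only faces visible from outside: viewpoints are distributed
#' quasi-uniformly on a sphere of radius `offsetFactor` times the mesh
#' bounding-sphere radius, and a face is kept when at least one ray from a
#' viewpoint reaches one of its three vertices or its centroid without being
#' blocked by another face. Partially occluded faces thus count as visible —
#' conservative retention avoids punching holes in the outer shell.
#'
#' With `componentwise = TRUE`, whole face-connected components containing
#' at least one visible face are retained instead of individual faces.
#'
#' @param mesh a [TriangleMesh-class], possibly with interior components.
#' @param nDirections number of viewpoints (default 256).
#' @param offsetFactor viewpoint sphere radius as a multiple of the
#'   bounding-sphere radius (default 1.5).
#' @param componentwise retain whole connected components (default `FALSE`).
#' @return The hollowed [TriangleMesh-class] (face subset of the input).
#' @examples
#' shells <- appendMeshes(sphereMesh(10, 1, id = "outer"),
#'                        sphereMesh(5, 1, id = "inner"))
#' h <- hollowMesh(shells, nDirections = 64)
#' nFaces(h) == nFaces(sphereMesh(10, 1))
#' @export
hollowMesh <- function(mesh, nDirections = 256, offsetFactor = 1.5,
                       componentwise = FALSE) {
  validObject(mesh)
  if (!is.numeric(nDirections) || length(nDirections) != 1L ||
      nDirections < 1)
    stop("nDirections must be a positive integer")
  v <- mesh@vertices
  center <- colMeans(apply(v, 2, range))
  radius <- sqrt(max(rowSums((v - matrix(center, nrow(v), 3,
                                         byrow = TRUE))^2)))
  views <- fibonacciSphere(as.integer(nDirections)) * (offsetFactor * radius)
  views <- views + matrix(center, nrow(views), 3, byrow = TRUE)
  vis <- cpp_visible_faces(v, mesh@faces, views)
  if (componentwise) {
    comp <- .faceComponents(mesh@faces)
    vis <- comp %in% unique(comp[vis])
  }
  if (!any(vis))
    stop("no face is visible from outside; cannot hollow this mesh")
  cleaned <- dropUnreferenced(v, mesh@faces[vis, , drop = FALSE])
  out <- TriangleMesh(cleaned$vertices, cleaned$faces, id = mesh@id,
                      side = mesh@side, meta = mesh@meta)
  validObject(out)
  out
}

# face connectivity via shared vertices (union-find)
.faceComponents <- function(faces) {
  m <- nrow(faces)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  byvert <- split(rep(seq_len(m), 3), as.vector(faces))
  for (grp in byvert) {
    if (length(grp) > 1L) {
      r <- find(grp[1])
      for (g in grp[-1]) parent[find(g)] <- r
    }
  }
  vapply(seq_len(m), find, integer(1))
}

#' Concatenate two meshes into one
#'
#' Utility for building multi-component fixtures (e.g. nested shells for
#' hollowing tests). Vertex indices of `b` are offset past those of `a`.
#'
#' @param a,b [TriangleMesh-class] objects.
#' @param id label for the combined mesh.
#' @return A [TriangleMesh-class] containing both surfaces.
#' @export
appendMeshes <- function(a, b, id = paste(a@id, b@id, sep = "+")) {
  TriangleMesh(rbind(a@vertices, b@vertices),
               rbind(a@faces, b@faces + nrow(a@vertices)),
               id = id, side = "unknown")
}
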