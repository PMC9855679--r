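crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotationAngle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

# unit face normals and (doubled) face areas; rows of zero-area faces are 0
faceNormals <- function(mesh, normalize = TRUE) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

#' Area-weighted per-vertex normals
#'
#' Each vertex normal is the normalised sum of the (area-weighted) normals of
#' its incident faces; the winding convention determines which way is
#' "outside".
#'
#' @param mesh a [TriangleMesh-class].
#' @return `n x 3` matrix of unit normals.
#' @export
vertexNormals <- function(mesh) {
  fn <- faceNormals(mesh, normalize = FALSE)  # area-weighted
  n <- matrix(0, nrow(mesh@vertices), 3)
  f <- mesh@faces
  for (c in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], f[, c])
      idx <- as.integer(rownames(acc))
      n[idx, k] <- n[idx, k] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Signed volume of a triangulated mesh
#'
#' Divergence-theorem volume `sum(det(v1, v2, v3)) / 6`. Only meaningful for
#' closed surfaces, where its sign tracks the winding orientation — used to
#' verify that mirroring preserves outward orientation.
#'
#' @param mesh a [TriangleMesh-class].
#' @return Signed volume (mm^3).
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
      a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Icosphere test mesh
#'
#' Unit-sphere triangulation by recursive subdivision of an icosahedron,
#' scaled to `radius` and centred at `center`. Used for oracles and fixtures
#' (concentric-shell hollowing, chordal-error distance checks).
#'
#' @param radius sphere radius (mm).
#' @param subdivisions recursive subdivision depth (0 = icosahedron,
#'   each level quadruples the face count).
#' @param center length-3 centre (mm).
#' @param id mesh label.
#' @return A closed [TriangleMesh-class] with outward-wound faces.
#' @examples
#' s <- sphereMesh(10, 1)
#' abs(meshVolume(s) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000) < 0.1
#' @export
sphereMesh <- function(radius = 1, subdivisions = 2, center = c(0, 0, 0),
                       id = "sphere") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env()
    key <- function(i, j) paste(min(i, j), max(i, j))
    getmid <- function(i, j) {
      k <- key(i, j)
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      i <- f[t, 1]; j <- f[t, 2]; k <- f[t, 3]
      a <- getmid(i, j); b <- getmid(j, k); c3 <- getmid(k, i)
      nf <- rbind(nf, c(i, a, c3), c(j, b, a), c(k, c3, b), c(a, b, c3))
    }
    f <- nf
  }
  TriangleMesh(v * radius + matrix(center, nrow(v), 3, byrow = TRUE), f,
               id = id)
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

# merge vertices identical after snapping to `digits` decimals; drop faces
# that become degenerate. Returns list(mesh, n_merged, n_dropped).
mergeDuplicateVertices <- function(vertices, faces, digits = 9) {
  key <- apply(round(vertices, digits), 1, paste, collapse = "/")
  first <- !duplicated(key)
  map <- match(key, key[first])
  keep <- vertices[first, , drop = FALSE]
  f <- matrix(map[faces], ncol = 3)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  # zero-area but index-distinct faces
  if (any(!degen)) {
    a <- keep[f[, 1], , drop = FALSE]
    e1 <- keep[f[, 2], , drop = FALSE] - a
    e2 <- keep[f[, 3], , drop = FALSE] - a
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    degen <- degen | rowSums(n^2) < 1e-24
  }
  list(vertices = keep, faces = f[!degen, , drop = FALSE],
       n_merged = nrow(vertices) - nrow(keep), n_dropped = sum(degen))
}

# drop vertices not referenced by any face; remap indices, track a set of
# vertex indices through the remap
dropUnreferenced <- function(vertices, faces, track = integer(0)) {
  used <- sort(unique(as.vector(faces)))
  map <- integer(nrow(vertices))
  map[used] <- seq_along(used)
  list(vertices = vertices[used, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3),
       track = map[track])
}

#' Check and repair face winding consistency
#'
#' Faces are consistently wound when every edge shared by two faces is
#' traversed in opposite directions by them. `isConsistentlyWound` checks;
#' `repairWinding` flips faces (breadth-first over the face adjacency graph)
#' until each connected component is consistent.
#'
#' @param mesh a [TriangleMesh-class].
#' @return `isConsistentlyWound`: logical. `repairWinding`: a repaired
#'   [TriangleMesh-class].
#' @export
isConsistentlyWound <- function(mesh) {
  f <- mesh@faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  # an edge traversed twice in the same direction betrays inconsistent winding
  !anyDuplicated(key)
}

#' @rdname isConsistentlyWound
#' @export
repairWinding <- function(mesh) {
  f <- mesh@faces
  m <- nrow(f)
  ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  edges <- rbind(cbind(f[, 1], f[, 2], seq_len(m)),
                 cbind(f[, 2], f[, 3], seq_len(m)),
                 cbind(f[, 3], f[, 1], seq_len(m)))
  k <- ekey(edges[, 1], edges[, 2])
  adj <- split(seq_len(nrow(edges)), k)
  visited <- logical(m)
  flipped <- logical(m)
  for (start in seq_len(m)) {
    if (visited[start]) next
    visited[start] <- TRUE
    queue <- start
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      fc <- f[cur, ]
      if (flipped[cur]) fc <- fc[c(1, 3, 2)]
      dirs <- rbind(fc[c(1, 2)], fc[c(2, 3)], fc[c(3, 1)])
      for (e in 1:3) {
        kk <- ekey(dirs[e, 1], dirs[e, 2])
        for (row in adj[[kk]]) {
          nb <- edges[row, 3]
          if (nb == cur || visited[nb]) next
          nfc <- f[nb, ]
          ndirs <- rbind(nfc[c(1, 2)], nfc[c(2, 3)], nfc[c(3, 1)])
          same <- any(ndirs[, 1] == dirs[e, 1] & ndirs[, 2] == dirs[e, 2])
          flipped[nb] <- same  # shared edge in the same direction -> flip
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  if (any(flipped))
    f[flipped, ] <- f[flipped, c(1, 3, 2), drop = FALSE]
  mesh@faces <- f
  mesh
}
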