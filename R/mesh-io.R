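#' Read a triangle mesh from STL or PLY
#'
#' Supports binary and ASCII STL and ASCII PLY. STL stores every facet with
#' its own three vertices, so duplicates are merged (coordinates identical
#' after snapping to 1e-9 mm) to recover connectivity; zero-area faces are
#' dropped with a message. Coordinates are taken to be millimetres — the
#' formats carry no unit information and only `"mm"` is accepted.
#'
#' A PLY `quality` vertex property (as written by [writeDistanceMap()]) is
#' preserved in `meta$quality`.
#'
#' @param path file path ending in `.stl` or `.ply`.
#' @param expectedUnits must be `"mm"`.
#' @param id mesh label; defaults to the file name without extension.
#' @param side `"left"`, `"right"` or `"unknown"`.
#' @return A validated [TriangleMesh-class].
#' @seealso [writeMesh()]
#' @export
readMesh <- function(path, expectedUnits = "mm", id = NULL,
                     side = "unknown") {
  if (!identical(expectedUnits, "mm"))
    stop("only millimetre meshes are supported (expectedUnits = 'mm')")
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  parsed <- switch(ext,
    stl = .readSTL(path),
    ply = .readPLY(path),
    stop("unsupported mesh format '.", ext, "' (use .stl or .ply)"))
  if (nrow(parsed$vertices) == 0L || nrow(parsed$faces) == 0L)
    stop("mesh file contains no geometry: ", path)
  merged <- mergeDuplicateVertices(parsed$vertices, parsed$faces)
  if (merged$n_dropped > 0)
    message(merged$n_dropped, " degenerate (zero-area) face(s) dropped")
  if (nrow(merged$faces) == 0L)
    stop("mesh is empty after cleaning: ", path)
  meta <- list()
  if (!is.null(parsed$quality)) meta$quality <- parsed$quality
  mesh <- TriangleMesh(merged$vertices, merged$faces, id = id, side = side,
                       meta = meta)
  if (!isConsistentlyWound(mesh)) {
    message("inconsistent face winding detected; repairing")
    mesh <- repairWinding(mesh)
  }
  mesh
}

#' Write a triangle mesh to STL or PLY
#'
#' `stl_binary` stores coordinates as 32-bit floats (round-trip within about
#' 1e-4 mm at bone scale); `stl_ascii` and `ply` print with enough digits to
#' round-trip within 1e-6 mm.
#'
#' @param mesh a valid [TriangleMesh-class].
#' @param path output file path.
#' @param format one of `"stl_binary"`, `"stl_ascii"`, `"ply"`; default
#'   guessed from the extension (`.stl` means binary).
#' @return Invisibly, `path`.
#' @export
writeMesh <- function(mesh, path,
                      format = c("auto", "stl_binary", "stl_ascii", "ply")) {
  validObject(mesh)
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl_binary", ply = "ply",
                     stop("cannot guess format from extension of ", path))
  switch(format,
    stl_binary = .writeSTLBinary(mesh, path),
    stl_ascii = .writeSTLAscii(mesh, path),
    ply = .writePLY(mesh, path))
  invisible(path)
}

.readSTL <- function(path) {
  size <- file.info(path)$size
  raw <- readBin(path, "raw", n = size)
  if (size >= 84) {
    nfac <- readBin(raw[81:84], "integer", size = 4, endian = "little")
    if (!is.na(nfac) && nfac > 0 && size == 84 + 50 * nfac)
      return(.parseSTLBinary(raw, nfac))
  }
  header <- rawToChar(raw[seq_len(min(80, size))])
  if (grepl("^\\s*solid", header)) return(.parseSTLAscii(path))
  stop("unreadable or truncated STL file: ", path)
}

.parseSTLBinary <- function(raw, nfac) {
  body <- matrix(raw[85:(84 + 50 * nfac)], nrow = 50)
  floats <- readBin(as.vector(body[1:48, , drop = FALSE]), "numeric",
                    n = 12L * nfac, size = 4, endian = "little")
  fm <- matrix(floats, nrow = 12)  # normal, v1, v2, v3 per column
  verts <- matrix(0, 3L * nfac, 3)
  verts[seq(1, 3 * nfac, 3), ] <- t(fm[4:6, , drop = FALSE])
  verts[seq(2, 3 * nfac, 3), ] <- t(fm[7:9, , drop = FALSE])
  verts[seq(3, 3 * nfac, 3), ] <- t(fm[10:12, , drop = FALSE])
  if (any(!is.finite(verts))) stop("non-finite coordinates in STL")
  list(vertices = verts,
       faces = matrix(seq_len(3L * nfac), ncol = 3, byrow = TRUE))
}

.parseSTLAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("malformed ASCII STL: vertex count not a multiple of 3 in ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"),
                 function(x) as.numeric(x[2:4]))
  verts <- do.call(rbind, nums)
  if (any(!is.finite(verts))) stop("non-finite coordinates in STL")
  list(vertices = verts,
       faces = matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE))
}

.writeSTLBinary <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces
  n <- faceNormals(mesh)
  nfac <- nrow(f)
  block <- t(cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE]))  # 12 floats per facet
  fraw <- writeBin(as.numeric(block), raw(), size = 4, endian = "little")
  fac <- matrix(as.raw(0), 50, nfac)
  fac[1:48, ] <- matrix(fraw, nrow = 48)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nfac), con, size = 4, endian = "little")
  writeBin(as.vector(fac), con)
  invisible(path)
}

.writeSTLAscii <- function(mesh, path) {
  v <- mesh@vertices
  f <- mesh@faces
  n <- faceNormals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", mesh@id), con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2],
                       n[i, 3]), con)
    writeLines("    outer loop", con)
    for (c in 1:3) {
      p <- v[f[i, c], ]
      writeLines(sprintf("      vertex %.9g %.9g %.9g", p[1], p[2], p[3]),
                 con)
    }
    writeLines(c("    endloop", "  endfacet"), con)
  }
  writeLines(paste("endsolid", mesh@id), con)
  invisible(path)
}

.writePLY <- function(mesh, path, quality = NULL, rgb = NULL) {
  v <- mesh@vertices
  f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  props <- c("property float x", "property float y", "property float z")
  cols <- format(v, digits = 9, trim = TRUE, scientific = FALSE)
  if (!is.null(quality)) {
    props <- c(props, "property float quality")
    cols <- cbind(cols, format(quality, digits = 9, trim = TRUE,
                               scientific = FALSE))
  }
  if (!is.null(rgb)) {
    props <- c(props, "property uchar red", "property uchar green",
               "property uchar blue")
    cols <- cbind(cols, rgb[, 1], rgb[, 2], rgb[, 3])
  }
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)), props,
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(cols, 1, paste, collapse = " "), con)
  writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

.readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  if (!grepl("ascii", lines[2]))
    stop("only ASCII PLY is supported: ", path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("malformed PLY header in ", path)
  header <- trimws(lines[seq_len(endh)])
  nv <- nf <- 0L
  vprops <- character(0)
  current <- ""
  for (h in header) {
    tok <- strsplit(h, "\\s+")[[1]]
    if (tok[1] == "element") {
      current <- tok[2]
      if (current == "vertex") nv <- as.integer(tok[3])
      if (current == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && current == "vertex" &&
               tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    }
  }
  if (nv < 1L || nf < 1L) stop("PLY file has no geometry: ", path)
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("truncated PLY file: ", path)
  vtab <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                as.numeric))
  if (ncol(vtab) != length(vprops)) stop("malformed PLY vertex rows in ", path)
  colnames(vtab) <- vprops
  ftab <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                 as.integer)
  faces <- do.call(rbind, lapply(ftab, function(x) {
    if (x[1] != 3L) stop("only triangular PLY faces are supported")
    x[2:4] + 1L
  }))
  if (max(faces) > nv || min(faces) < 1L)
    stop("PLY face references vertex index out of range")
  out <- list(vertices = unname(vtab[, c("x", "y", "z"), drop = FALSE]),
              faces = faces)
  if ("quality" %in% vprops) out$quality <- unname(vtab[, "quality"])
  out
}

#' Read landmarks from a sidecar JSON file
#'
#' Expected schema:
#' `{"mesh_id": str, "landmarks": {"sym_sup": [x,y,z], "sym_inf": [x,y,z],
#' "obt_med": [x,y,z]}}` with coordinates in mm. The three points must be
#' present and non-collinear.
#'
#' @param path JSON file path.
#' @return A validated [LandmarkSet-class].
#' @seealso [writeLandmarks()]
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  js <- jsonlite::fromJSON(path)
  if (is.null(js$mesh_id) || is.null(js$landmarks))
    stop("landmark file must contain 'mesh_id' and 'landmarks': ", path)
  missing <- setdiff(.LANDMARK_NAMES, names(js$landmarks))
  if (length(missing))
    stop("landmark file is missing: ", paste(missing, collapse = ", "))
  LandmarkSet(js$mesh_id, js$landmarks[.LANDMARK_NAMES])
}

#' Write landmarks to a sidecar JSON file
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
writeLandmarks <- function(landmarks, path) {
  validObject(landmarks)
  p <- landmarks@points
  obj <- list(mesh_id = landmarks@meshId,
              landmarks = stats::setNames(
                lapply(seq_len(3), function(i) as.numeric(p[i, ])),
                rownames(p)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
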