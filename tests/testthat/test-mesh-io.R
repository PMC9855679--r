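test_that("meshes round-trip through every supported format", {
  dir <- withr::local_tempdir()
  mesh <- sphereMesh(10.37, 2, center = c(1.2, -3.4, 5.6))
  tol <- c(stl_binary = 1e-4, stl_ascii = 1e-6, ply = 1e-6)
  for (fmt in names(tol)) {
    ext <- if (fmt == "ply") "ply" else "stl"
    path <- file.path(dir, paste0("m_", fmt, ".", ext))
    writeMesh(mesh, path, format = fmt)
    back <- readMesh(path)
    expect_identical(nVertices(back), nVertices(mesh))
    expect_identical(nFaces(back), nFaces(mesh))
    # topology preserved: every face maps to an original face after
    # matching vertices by position
    map <- vapply(seq_len(nVertices(back)), function(i) {
      which.min(colSums((t(vertices(mesh)) - vertices(back)[i, ])^2))
    }, integer(1))
    expect_setequal(
      apply(matrix(map[faces(back)], ncol = 3), 1,
            function(f) paste(sort(f), collapse = "-")),
      apply(faces(mesh), 1, function(f) paste(sort(f), collapse = "-")))
    expect_lt(max(abs(vertices(back)[order(map), ] -
                        vertices(mesh)[sort(map), ])), tol[[fmt]])
  }
})

test_that("ASCII and binary STL of the same solid parse identically", {
  dir <- withr::local_tempdir()
  tetra <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                              c(0, 0, 1)),
                        rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3),
                              c(2, 3, 4)), id = "tetra")
  pa <- file.path(dir, "a.stl")
  pb <- file.path(dir, "b.stl")
  writeMesh(tetra, pa, format = "stl_ascii")
  writeMesh(tetra, pb, format = "stl_binary")
  a <- readMesh(pa)
  b <- readMesh(pb)
  expect_equal(vertices(a), vertices(b), tolerance = 1e-6)
  expect_identical(faces(a), faces(b))
})

test_that("a cube writes twelve STL facets and duplicates merge on read", {
  dir <- withr::local_tempdir()
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  cube <- TriangleMesh(corners, rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6)), id = "cube")
  path <- file.path(dir, "cube.stl")
  writeMesh(cube, path, format = "stl_binary")
  # binary STL layout: 80-byte header + 4-byte count + 50 bytes per facet
  expect_identical(file.info(path)$size, 84 + 50 * 12)
  back <- readMesh(path)
  expect_identical(nVertices(back), 8L)  # 36 stored vertices merged to 8
  expect_identical(nFaces(back), 12L)
})

test_that("malformed mesh files are rejected with informative errors", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.stl")
  writeBin(as.raw(1:40), bad)
  expect_error(readMesh(bad), "unreadable|truncated")
  ply <- file.path(dir, "bad.ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "3 0 1 3"), ply)  # index 3 == #vertices
  expect_error(readMesh(ply), "out of range")
  expect_error(readMesh(file.path(dir, "missing.stl")), "does not exist")
  expect_error(TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                            matrix(c(1L, 2L, 4L), 1)), "out of range")
  expect_error(TriangleMesh(rbind(c(0, 0, NA), c(1, 0, 0), c(0, 1, 0)),
                            matrix(c(1L, 2L, 3L), 1)), "finite")
})

test_that("degenerate faces are dropped and validation is idempotent", {
  dir <- withr::local_tempdir()
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(0.5, 0, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))  # third face is collinear
  path <- file.path(dir, "degen.stl")
  writeMesh(TriangleMesh(v, f), path, format = "stl_ascii")
  expect_message(mesh <- readMesh(path), "degenerate")
  expect_identical(nFaces(mesh), 2L)
  # validating an already-validated mesh changes nothing and stays silent
  before <- list(vertices(mesh), faces(mesh))
  expect_silent(validObject(mesh))
  expect_identical(list(vertices(mesh), faces(mesh)), before)
})

test_that("landmark files follow the sidecar JSON schema", {
  dir <- withr::local_tempdir()
  lm <- LandmarkSet("pubis_L", list(sym_sup = c(0.5, 10, 0),
                                    sym_inf = c(0.25, -10.5, 1),
                                    obt_med = c(15, 0.75, 2)))
  path <- file.path(dir, "lm.json")
  writeLandmarks(lm, path)
  back <- readLandmarks(path)
  expect_identical(meshId(back), "pubis_L")
  expect_equal(landmarkPoints(back), landmarkPoints(lm))

  js <- jsonlite::fromJSON(path)
  js$landmarks$obt_med <- NULL
  p2 <- file.path(dir, "missing.json")
  jsonlite::write_json(js, p2, auto_unbox = TRUE)
  expect_error(readLandmarks(p2), "obt_med")

  collinear <- list(sym_sup = c(0, 0, 0), sym_inf = c(1, 1, 1),
                    obt_med = c(2, 2, 2))
  p3 <- file.path(dir, "collinear.json")
  jsonlite::write_json(list(mesh_id = "x", landmarks = collinear), p3,
                       auto_unbox = TRUE)
  expect_error(readLandmarks(p3), "collinear|degenerate")
})

test_that("landmark validity rejects near-degenerate geometry", {
  expect_error(LandmarkSet("x", list(sym_sup = c(0, 0, 0),
                                     sym_inf = c(0, 0, 0),
                                     obt_med = c(1, 0, 0))),
               "degenerate")
  expect_error(LandmarkSet("x", list(sym_sup = c(0, 0, 0),
                                     sym_inf = c(1, 0, 0))),
               "missing landmark")
})
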