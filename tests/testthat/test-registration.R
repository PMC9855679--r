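make_lm <- function(pts, id = "lm") {
  rownames(pts) <- c("sym_sup", "sym_inf", "obt_med")
  LandmarkSet(id, pts)
}

test_that("landmark alignment recovers exact rigid correspondences", {
  lm <- make_lm(rbind(c(0, 10, 0), c(0, -10, 0), c(15, 0, 2)))
  tf <- landmarkAlign(lm, lm)
  expect_equal(rotation(tf), diag(3), tolerance = 1e-12)
  expect_equal(translation(tf), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(attr(tf, "residualRMS"), 0, tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:10) {
    R <- random_rotation()
    t <- runif(3, -20, 20)
    moved <- make_lm(landmarkPoints(lm) %*% t(R) +
                       matrix(t, 3, 3, byrow = TRUE))
    rec <- landmarkAlign(lm, moved)
    expect_equal(rotation(rec), R, tolerance = 1e-9)
    expect_equal(translation(rec), t, tolerance = 1e-9)
    expect_lt(attr(rec, "residualRMS"), 1e-9)
  }
})

test_that("mirror-image correspondences never produce a reflection", {
  # fixed landmarks are a mirror image of the moving ones. Three labelled
  # points are always coplanar, so a proper rotation can reproduce the
  # reflection exactly (compose it with the mirror across the points' own
  # plane); the solution must be that rotation — det +1, residual zero —
  # and never an improper det = -1 fit
  moving <- make_lm(rbind(c(0, 10, 0), c(0, -10, 0), c(15, 0, 6)))
  pts <- landmarkPoints(moving)
  pts[, 1] <- -pts[, 1]
  fixed <- make_lm(pts)
  tf <- landmarkAlign(moving, fixed)
  expect_equal(det(rotation(tf)), 1, tolerance = 1e-9)
  # brute-force oracle over rigid parameterisations agrees on the optimum
  set.seed(11)
  obj <- function(par) {
    R <- rotvec_to_matrix(par[1:3])
    P <- landmarkPoints(moving) %*% t(R) +
      matrix(par[4:6], 3, 3, byrow = TRUE)
    sqrt(mean(rowSums((P - landmarkPoints(fixed))^2)))
  }
  best <- Inf
  for (i in 1:200) {
    o <- optim(c(rnorm(3, 0, pi / 2), rnorm(3, 0, 10)), obj,
               control = list(maxit = 400))
    best <- min(best, o$value)
  }
  expect_lte(attr(tf, "residualRMS"), best + 1e-6)
  expect_lt(attr(tf, "residualRMS"), 1e-9)
})

test_that("landmark alignment validates its inputs", {
  lm <- make_lm(rbind(c(0, 10, 0), c(0, -10, 0), c(15, 0, 2)))
  expect_error(landmarkAlign(lm, "not landmarks"))
})

test_that("ICP on an exact copy is a fixed point", {
  mesh <- small_shell(5)$right
  res <- icpRegister(mesh, mesh)
  expect_lt(res@finalRMS, 1e-9)
  expect_lte(res@iterations, 2L)
  expect_true(res@converged)
  expect_equal(rotation(res@transform), diag(3), tolerance = 1e-9)
})

test_that("ICP recovers a known rigid transform via landmark seeding", {
  ind <- small_shell(9, subdiv = 3)
  fixed <- ind$right
  th <- 10 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  truth <- RigidTransform(Rz, c(5, 0, 0))
  moving <- applyTransform(fixed, invertTransform(truth))
  movingLm <- applyTransform(ind$rightLm, invertTransform(truth))
  res <- icpRegister(moving, fixed,
                     init = landmarkAlign(movingLm, ind$rightLm))
  expect_lt(res@finalRMS, 1e-6)
  expect_lt(max(abs(rotation(res@transform) - Rz)), 1e-6)
  expect_lt(max(abs(translation(res@transform) - c(5, 0, 0))), 1e-6)
})

test_that("ICP RMS lands in the Monte-Carlo bracket for normal-noise surfaces", {
  # vertices displaced along normals by sigma = 0.1 mm; the point-to-surface
  # RMS of the registered result must stay close to sigma
  base <- sphereMesh(10, 2)
  nrm <- vertexNormals(base)
  for (seed in 1:20) {
    set.seed(seed)
    noisy <- TriangleMesh(vertices(base) + nrm * rnorm(nVertices(base), 0, 0.1),
                          faces(base))
    res <- icpRegister(noisy, base)
    expect_gt(res@finalRMS, 0.05)
    expect_lt(res@finalRMS, 0.15)
  }
})

test_that("ICP stays rigid and its RMS trajectory is monotone", {
  for (seed in 1:5) {
    ind <- small_shell(seed)
    res <- icpRegister(mirrorMesh(ind$left), ind$right,
                       init = landmarkAlign(mirrorLandmarks(ind$leftLm),
                                            ind$rightLm))
    R <- rotation(res@transform)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    expect_true(all(diff(res@rmsTrajectory) <= 1e-9))
  }
})

test_that("registration is invariant to a rigid pre-transform of the moving mesh", {
  ind <- small_shell(13)
  moving <- mirrorMesh(ind$left)
  movingLm <- mirrorLandmarks(ind$leftLm)
  ref <- superimpose(moving, ind$right, movingLm, ind$rightLm)$rms
  set.seed(3)
  for (rep in 1:3) {
    pre <- RigidTransform(random_rotation(), runif(3, -30, 30))
    moved <- applyTransform(moving, pre)
    movedLm <- applyTransform(movingLm, pre)
    got <- superimpose(moved, ind$right, movedLm, ind$rightLm)$rms
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("ICP matches a random-restart rigid optimisation oracle", {
  # tiny moving mesh (<= 50 vertices): the ICP solution must be at least as
  # good as the best of 1000 random rigid starts with local polish
  tiny <- generateIndividual(21, assemblageConfig(meshSubdivisions = 2,
                                                  poseRandomisation = FALSE))
  fixed <- tiny$right
  f <- faces(fixed)
  fkeep <- f[apply(f <= 50, 1, all), , drop = FALSE]  # crop: first 50 verts
  crop <- TriangleMesh(vertices(fixed)[1:50, ], fkeep, id = "crop")
  set.seed(99)
  pre <- RigidTransform(random_rotation(), runif(3, -10, 10))
  moving <- applyTransform(crop, pre)
  movingLm <- applyTransform(tiny$rightLm, pre)
  res <- icpRegister(moving, fixed,
                     init = landmarkAlign(movingLm, tiny$rightLm),
                     params = icpParams(tolMM = 1e-9))
  best <- oracle_best_rigid_rms(moving, fixed, restarts = 1000)
  expect_lte(res@finalRMS, best + 1e-6)
})

test_that("ICP parameter validation and non-convergence reporting behave", {
  expect_error(icpParams(maxIterations = 0), "maxIterations")
  expect_error(icpParams(tolMM = 0), "tolMM")
  ind <- small_shell(2)
  res <- icpRegister(mirrorMesh(ind$left), ind$right,
                     init = landmarkAlign(mirrorLandmarks(ind$leftLm),
                                          ind$rightLm),
                     params = icpParams(maxIterations = 2))
  expect_false(res@converged)
  expect_identical(res@iterations, 2L)
})

test_that("vertex-correspondence mode gives a comparable registration", {
  ind <- small_shell(4)
  fixed <- ind$right
  moving <- mirrorMesh(ind$left)
  lmM <- mirrorLandmarks(ind$leftLm)
  surf <- superimpose(moving, fixed, lmM, ind$rightLm)$rms
  vert <- superimpose(moving, fixed, lmM, ind$rightLm,
                      params = icpParams(correspondence = "vertex"))$rms
  expect_true(is.finite(vert) && vert > 0)
  expect_lt(abs(vert - surf) / surf, 0.5)
})
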