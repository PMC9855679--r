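#' Least-squares rigid alignment (Kabsch) of corresponding points
#'
#' Internal workhorse: the proper rigid transform minimising
#' `sum |R x_i + t - y_i|^2`. Reflections are excluded by flipping the sign
#' of the smallest singular direction when the raw SVD solution has
#' determinant -1, so the result is always a rotation even when a reflection
#' would fit better.
#'
#' @param X,Y `n x 3` matrices of corresponding points (`X` moving, `Y`
#'   fixed), `n >= 3`.
#' @return A [RigidTransform-class] mapping `X` onto `Y`.
#' @keywords internal
kabsch <- function(X, Y) {
  cx <- colMeans(X)
  cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  RigidTransform(R, cy - as.numeric(R %*% cx))
}

#' Coarse alignment from three named landmarks
#'
#' Computes the least-squares proper rigid transform (Kabsch on the three
#' correspondences, matched by landmark name; reflection excluded) mapping
#' the moving landmarks onto the fixed landmarks. This seeds the ICP
#' refinement — it brings the mirrored left model roughly onto the right
#' model so that nearest-point correspondences start anatomically sensible.
#'
#' @param movingLm,fixedLm [LandmarkSet-class] objects (the moving set
#'   normally comes from the mirrored left model).
#' @return A [RigidTransform-class] with attribute `residualRMS`: the RMS
#'   (mm) of the landmark residuals after alignment (0 for noiseless
#'   correspondences of a rigid motion).
#' @examples
#' lm <- LandmarkSet("a", list(sym_sup = c(0, 10, 0), sym_inf = c(0, -10, 0),
#'                             obt_med = c(15, 0, 2)))
#' tf <- landmarkAlign(lm, lm)
#' attr(tf, "residualRMS")  # 0
#' @export
landmarkAlign <- function(movingLm, fixedLm) {
  validObject(movingLm)
  validObject(fixedLm)
  X <- movingLm@points[.LANDMARK_NAMES, , drop = FALSE]
  Y <- fixedLm@points[.LANDMARK_NAMES, , drop = FALSE]
  tf <- kabsch(X, Y)
  res <- applyTransform(X, tf) - Y
  attr(tf, "residualRMS") <- sqrt(mean(rowSums(res^2)))
  tf
}

#' ICP iteration parameters
#'
#' Defaults reflect the protocol's intent of using whole surfaces: every
#' moving vertex participates (no sampling below `sampleSize`), no
#' correspondence-distance trimming, and iteration stops when the RMS
#' improves by less than `tolMM` or after `maxIterations`.
#'
#' @param maxIterations iteration cap (default 100).
#' @param tolMM RMS-change convergence tolerance in mm (default 1e-6).
#' @param maxCorrespondenceDistance drop correspondences farther than this
#'   (mm); default `Inf` (no trimming).
#' @param sampleSize use at most this many moving vertices, deterministic
#'   even subsample (default `Inf`: all vertices).
#' @param correspondence `"surface"`: closest point on the fixed
#'   triangulated surface (resolution-independent, default); `"vertex"`:
#'   closest fixed vertex.
#' @return A named list of validated parameters.
#' @export
icpParams <- function(maxIterations = 100, tolMM = 1e-6,
                      maxCorrespondenceDistance = Inf, sampleSize = Inf,
                      correspondence = c("surface", "vertex")) {
  if (maxIterations < 1) stop("maxIterations must be >= 1")
  if (tolMM <= 0) stop("tolMM must be > 0")
  if (maxCorrespondenceDistance <= 0)
    stop("maxCorrespondenceDistance must be > 0")
  list(maxIterations = as.integer(maxIterations), tolMM = tolMM,
       maxCorrespondenceDistance = maxCorrespondenceDistance,
       sampleSize = sampleSize,
       correspondence = match.arg(correspondence))
}

.closestOnTarget <- function(P, fixed, correspondence) {
  if (correspondence == "surface") {
    cp <- cpp_closest_on_surface(P, fixed@vertices, fixed@faces)
    list(points = cp$points, dist = cp$dist)
  } else {
    fv <- fixed@vertices
    idx <- vapply(seq_len(nrow(P)), function(i) {
      which.min(colSums((t(fv) - P[i, ])^2))
    }, integer(1))
    pts <- fv[idx, , drop = FALSE]
    list(points = pts, dist = sqrt(rowSums((P - pts)^2)))
  }
}

#' Iterative-closest-point rigid refinement
#'
#' Refines an initial transform by alternating (a) nearest-point
#' correspondence from each moving vertex to the fixed surface and (b) the
#' closed-form rigid update (Kabsch) for those correspondences, until the
#' RMS change drops below `params$tolMM` or `params$maxIterations` is
#' reached. The update is always a proper rigid motion — no scaling can be
#' introduced at any iteration — and the recorded RMS trajectory is
#' monotonically non-increasing. Registration is one-way: the moving
#' (mirrored left) model is transformed onto the fixed (right) model.
#'
#' Nearest-point ties between faces are broken by the lowest face index, so
#' results are deterministic across runs.
#'
#' @param moving,fixed [TriangleMesh-class] objects.
#' @param init initial [RigidTransform-class], normally from
#'   [landmarkAlign()] (default identity).
#' @param params from [icpParams()].
#' @return A [RegistrationResult-class]. Non-convergence within the
#'   iteration cap is reported via `converged = FALSE`, not an error.
#' @examples
#' s <- sphereMesh(10, 1)
#' r <- icpRegister(s, s)
#' r@finalRMS  # 0
#' @export
icpRegister <- function(moving, fixed, init = identityTransform(),
                        params = icpParams()) {
  validObject(moving)
  validObject(fixed)
  validObject(init)
  X0 <- moving@vertices
  if (is.finite(params$sampleSize) && params$sampleSize < nrow(X0)) {
    keep <- unique(round(seq(1, nrow(X0), length.out = params$sampleSize)))
    X0 <- X0[keep, , drop = FALSE]
  }
  tf <- init
  traj <- numeric(0)
  prevRMS <- Inf
  converged <- FALSE
  iters <- 0L
  # one correspondence query per iteration: the query at the current
  # transform both records its RMS and feeds the next Kabsch update, whose
  # result can only lower the point-to-surface RMS (monotone trajectory)
  for (it in seq_len(params$maxIterations)) {
    iters <- it
    P <- applyTransform(X0, tf)
    corr <- .closestOnTarget(P, fixed, params$correspondence)
    rmsNow <- rms(corr$dist)
    traj <- c(traj, rmsNow)
    if (abs(prevRMS - rmsNow) < params$tolMM) {
      converged <- TRUE
      break
    }
    prevRMS <- rmsNow
    if (it == params$maxIterations) break  # keep transform and RMS in step
    use <- corr$dist <= params$maxCorrespondenceDistance
    if (sum(use) < 3L)
      stop("fewer than 3 correspondences within maxCorrespondenceDistance")
    upd <- kabsch(X0[use, , drop = FALSE], corr$points[use, , drop = FALSE])
    stopifnot(abs(det(upd@rotation) - 1) < 1e-9)  # rigid, never a reflection
    tf <- upd
  }
  new("RegistrationResult", transform = tf, iterations = iters,
      converged = converged, finalRMS = traj[length(traj)],
      rmsTrajectory = traj)
}

#' Full superimposition of one mesh onto another
#'
#' Convenience wrapper running the whole registration stage for one pair:
#' landmark-seeded coarse alignment, ICP refinement, then the per-vertex
#' point-to-surface distance field of the registered moving model against
#' the fixed model and its RMS.
#'
#' @param moving,fixed [TriangleMesh-class] objects (the moving mesh should
#'   already be mirrored when comparing a left to a right element).
#' @param movingLm,fixedLm matching [LandmarkSet-class] objects, or `NULL`
#'   to start ICP from the identity.
#' @param params [icpParams()].
#' @return A list with elements `registration` ([RegistrationResult-class]),
#'   `field` ([DistanceField-class]), `rms` (mm) and `registered` (the
#'   transformed moving [TriangleMesh-class]).
#' @export
superimpose <- function(moving, fixed, movingLm = NULL, fixedLm = NULL,
                        params = icpParams()) {
  init <- if (is.null(movingLm) || is.null(fixedLm)) identityTransform()
          else landmarkAlign(movingLm, fixedLm)
  reg <- icpRegister(moving, fixed, init = init, params = params)
  registered <- applyTransform(moving, reg@transform)
  field <- surfaceDistances(registered, fixed)
  list(registration = reg, field = field, rms = rms(field),
       registered = registered)
}
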