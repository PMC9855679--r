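# Independent geometric oracles and fixture builders, kept deliberately
# separate from the package's own algorithms.

# Brute-force point-to-triangle distance: minimum over the in-plane
# projection (when its barycentric coordinates are all non-negative), the
# three edge segments and the three vertices.
oracle_point_triangle <- function(p, a, b, c) {
  cand <- list(a, b, c)
  seg <- function(p, q0, q1) {
    d <- q1 - q0
    t <- sum((p - q0) * d) / sum(d * d)
    q0 + max(0, min(1, t)) * d
  }
  cand <- c(cand, list(seg(p, a, b), seg(p, b, c), seg(p, a, c)))
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  nn <- sum(n * n)
  if (nn > 0) {
    proj <- p - sum((p - a) * n) / nn * n
    # barycentric test of the projection
    m <- cbind(b - a, c - a)
    uv <- tryCatch(solve(crossprod(m), crossprod(m, proj - a)),
                   error = function(e) NULL)
    if (!is.null(uv) && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1)
      cand <- c(cand, list(as.numeric(proj)))
  }
  min(vapply(cand, function(q) sqrt(sum((p - q)^2)), numeric(1)))
}

# All-triangles scan using the oracle above.
oracle_surface_distances <- function(points, mesh) {
  v <- vertices(mesh)
  f <- faces(mesh)
  apply(points, 1, function(p) {
    min(vapply(seq_len(nrow(f)), function(j) {
      oracle_point_triangle(p, v[f[j, 1], ], v[f[j, 2], ], v[f[j, 3], ])
    }, numeric(1)))
  })
}

# Uniformly-ish random proper rotation (QR of a Gaussian matrix, det fixed).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotvec_to_matrix <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  ax <- r / th
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Random-restart rigid optimisation oracle: best point-to-surface RMS found
# over `restarts` random rigid starts, polishing the most promising starts
# with Nelder-Mead over (rotation vector, translation).
oracle_best_rigid_rms <- function(moving, fixed, restarts = 1000,
                                  polish = 10, shift = 10) {
  X <- vertices(moving)
  obj <- function(par) {
    R <- rotvec_to_matrix(par[1:3])
    P <- X %*% t(R) + matrix(par[4:6], nrow(X), 3, byrow = TRUE)
    rms(surfaceDistances(TriangleMesh(P, faces(moving)), fixed)@distances)
  }
  starts <- t(replicate(restarts, c(rnorm(3, 0, pi / 2),
                                    runif(3, -shift, shift))))
  vals <- apply(starts, 1, obj)
  best <- min(vals)
  for (i in order(vals)[seq_len(polish)]) {
    o <- optim(starts[i, ], obj, control = list(maxit = 300))
    best <- min(best, o$value)
  }
  best
}

# Exact two-sided Mann-Whitney p-value by enumeration of all assignments of
# the pooled ranks to the first sample (tie-free samples only).
oracle_exact_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Small open-shell fixture: a coarse individual from the synthetic module.
small_shell <- function(seed = 1, subdiv = 2, asym = 0.3) {
  generateIndividual(seed,
                     assemblageConfig(meshSubdivisions = subdiv,
                                      sigmaAsym = asym,
                                      poseRandomisation = FALSE))
}
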