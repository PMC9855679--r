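#' Configuration for a synthetic assemblage
#'
#' Defines the study conditions the generator emulates: per group (the
#' analogue of a sex group), `nPaired` individuals contribute a left and a
#' right model and `nUnpairedLeft` extra individuals contribute a left model
#' only, so the all-against-all design per group is
#' `(nPaired + nUnpairedLeft) x nPaired` comparisons. The defaults replicate
#' a 20 + 2 per-group, two-group design: 440 superimpositions per group,
#' 880 in total, 40 matches and 840 mismatches.
#'
#' `sigmaBetween` is the RMS amplitude (mm) of the smooth per-individual
#' shape deformation shared by both sides of an individual;
#' `sigmaAsym` the RMS amplitude of the independent left-right asymmetry
#' deformation added to the right side. The defaults (2.0 vs 0.3 mm) encode
#' the variance structure that drives pair-matching: within-individual
#' bilateral asymmetry small relative to between-individual shape
#' variation.
#'
#' @param nPaired paired individuals per group (default 20).
#' @param nUnpairedLeft unpaired left models per group (default 2).
#' @param groups group labels (default `c("m", "f")`).
#' @param sigmaBetween between-individual deformation amplitude, mm RMS
#'   (default 2.0).
#' @param sigmaAsym bilateral-asymmetry deformation amplitude, mm RMS
#'   (default 0.3).
#' @param meshSubdivisions template grid density (default 4: about 220
#'   vertices / 360 faces per model).
#' @param poseRandomisation apply a random rigid pose to each exported
#'   model (default `TRUE`; registration must undo it).
#' @param seed master seed; per-individual seeds are spawned from it
#'   deterministically.
#' @return A validated config list.
#' @export
assemblageConfig <- function(nPaired = 20, nUnpairedLeft = 2,
                             groups = c("m", "f"), sigmaBetween = 2.0,
                             sigmaAsym = 0.3, meshSubdivisions = 4,
                             poseRandomisation = TRUE, seed = 1) {
  if (nPaired < 1) stop("nPaired must be >= 1")
  if (nUnpairedLeft < 0) stop("nUnpairedLeft must be >= 0")
  if (sigmaBetween < 0 || sigmaAsym < 0)
    stop("deformation amplitudes must be >= 0")
  if (meshSubdivisions < 2) stop("meshSubdivisions must be >= 2")
  if (anyDuplicated(groups)) stop("group labels must be unique")
  list(nPaired = as.integer(nPaired),
       nUnpairedLeft = as.integer(nUnpairedLeft),
       groups = as.character(groups), sigmaBetween = sigmaBetween,
       sigmaAsym = sigmaAsym, meshSubdivisions = as.integer(meshSubdivisions),
       poseRandomisation = isTRUE(poseRandomisation),
       seed = as.integer(seed))
}

# Template: a curved plate-like open shell, ~40 x 30 x 15 mm, with a
# foramen-like notch cut out, plus the indices of the three landmark
# vertices (tracked through all deformations).
.boneTemplate <- function(subdiv) {
  nu <- 4L * subdiv + 1L
  nv <- 3L * subdiv + 1L
  u <- rep(seq(0, 1, length.out = nu), times = nv)
  v <- rep(seq(0, 1, length.out = nv), each = nu)
  verts <- cbind(40 * (u - 0.5), 30 * (v - 0.5),
                 15 * sin(pi * u) * sin(pi * v))
  idx <- function(i, j) (j - 1L) * nu + i
  i <- rep(seq_len(nu - 1L), times = nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  f <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
             cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  # foramen-like notch: remove faces whose centroid falls in a (u,v) disc
  uc <- (u[f[, 1]] + u[f[, 2]] + u[f[, 3]]) / 3
  vc <- (v[f[, 1]] + v[f[, 2]] + v[f[, 3]]) / 3
  keep <- (uc - 0.68)^2 + (vc - 0.35)^2 > 0.12^2
  f <- f[keep, , drop = FALSE]
  nearest <- function(uu, vv) which.min((u - uu)^2 + (v - vv)^2)
  lmIdx <- c(sym_sup = nearest(0.10, 0.85), sym_inf = nearest(0.10, 0.15),
             obt_med = nearest(0.50, 0.35))
  cleaned <- dropUnreferenced(verts, f, track = lmIdx)
  list(vertices = cleaned$vertices, faces = cleaned$faces,
       lmIdx = stats::setNames(cleaned$track, names(lmIdx)))
}

# Smooth random displacement field: sum of `nBasis` low-frequency
# trigonometric terms (wavelengths 15-45 mm, comparable to the template
# extent so the field has genuine non-rigid content). The amplitude is
# normalised on the field's non-rigid content: the best-fit rigid motion of
# the displaced points is removed before scaling to `sigma`, since any
# rigid component is invisible to the registration stage. Returns a
# function.
.randomField <- function(pts, sigma, nBasis = 10) {
  dirs <- matrix(stats::rnorm(3 * nBasis), nBasis, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  wl <- stats::runif(nBasis, 15, 45)
  wdir <- matrix(stats::rnorm(3 * nBasis), nBasis, 3)
  wdir <- wdir / sqrt(rowSums(wdir^2))
  waves <- wdir * (2 * pi / wl)
  phases <- stats::runif(nBasis, 0, 2 * pi)
  amps <- stats::rnorm(nBasis)
  field <- function(p) {
    d <- matrix(0, nrow(p), 3)
    for (k in seq_len(nBasis)) {
      s <- sin(p %*% waves[k, ] + phases[k])
      d <- d + amps[k] * as.numeric(s) %o% dirs[k, ]
    }
    d
  }
  if (sigma > 0) {
    displaced <- pts + field(pts)
    resid <- displaced - applyTransform(pts, kabsch(pts, displaced))
    cur <- sqrt(mean(rowSums(resid^2)))
    scale <- if (cur > 0) sigma / cur else 0
  } else scale <- 0
  function(p) field(p) * scale
}

.randomPose <- function(maxAngleDeg = 25, maxShiftMM = 15) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, maxAngleDeg * pi / 180)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  RigidTransform(R, stats::runif(3, -maxShiftMM, maxShiftMM))
}

#' Generate one synthetic individual (left + right models)
#'
#' The individual's shape is the template deformed by a smooth random field
#' of amplitude `sigmaBetween` (shared by both sides). The right side
#' additionally receives an independent smooth field of amplitude
#' `sigmaAsym` — the bilateral asymmetry. The left model is the mirror (in
#' x) of the individual's left-side shape, as a real left element would be;
#' with `sigmaAsym = 0` and pose randomisation off, re-mirroring the left
#' reproduces the right exactly. Landmarks are three fixed template
#' vertices tracked through the deformations.
#'
#' @param seed integer seed for this individual.
#' @param config from [assemblageConfig()].
#' @param id individual label.
#' @return List with `left`, `right` ([TriangleMesh-class]) and `leftLm`,
#'   `rightLm` ([LandmarkSet-class]).
#' @export
generateIndividual <- function(seed, config = assemblageConfig(),
                               id = "ind") {
  tpl <- .boneTemplate(config$meshSubdivisions)
  set.seed(as.integer(seed))
  fieldBetween <- .randomField(tpl$vertices, config$sigmaBetween)
  fieldAsym <- .randomField(tpl$vertices, config$sigmaAsym)
  indiv <- tpl$vertices + fieldBetween(tpl$vertices)
  rightV <- indiv + fieldAsym(indiv)
  leftV <- indiv
  leftV[, 1] <- -leftV[, 1]
  leftF <- tpl$faces[, c(1L, 3L, 2L), drop = FALSE]  # preserve orientation
  left <- TriangleMesh(leftV, leftF, id = paste0(id, "_L"), side = "left")
  right <- TriangleMesh(rightV, tpl$faces, id = paste0(id, "_R"),
                        side = "right")
  leftLm <- LandmarkSet(left@id, {
    p <- leftV[tpl$lmIdx, , drop = FALSE]
    rownames(p) <- names(tpl$lmIdx)
    p
  })
  rightLm <- LandmarkSet(right@id, {
    p <- rightV[tpl$lmIdx, , drop = FALSE]
    rownames(p) <- names(tpl$lmIdx)
    p
  })
  if (config$poseRandomisation) {
    poseL <- .randomPose()
    poseR <- .randomPose()
    left <- applyTransform(left, poseL)
    leftLm <- applyTransform(leftLm, poseL)
    right <- applyTransform(right, poseR)
    rightLm <- applyTransform(rightLm, poseR)
  }
  list(left = left, right = right, leftLm = leftLm, rightLm = rightLm)
}

# deterministic per-individual seed spawning (kept below 2^31)
.spawnSeed <- function(master, group, index) {
  h <- sum(utf8ToInt(group)) %% 1000L
  as.integer((as.numeric(master) * 48271 + h * 7919 + index * 104729) %%
               2147483629) + 1L
}

#' Generate a synthetic assemblage on disk
#'
#' Writes, per group, `nPaired` left/right pairs plus `nUnpairedLeft` extra
#' left models (their rights withheld) under `outDir`:
#' `meshes/{id}_{L|R}.stl`, `landmarks/{id}_{L|R}.json`, `truth.csv`
#' (the paired ids only) and `manifest.json` (ids, per-individual seeds,
#' config echo, md5 checksums). Regeneration with the same config and seed
#' reproduces identical files.
#'
#' @param config from [assemblageConfig()].
#' @param outDir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @seealso [runPipeline()]
#' @export
generateAssemblage <- function(config = assemblageConfig(), outDir) {
  dir.create(file.path(outDir, "meshes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "landmarks"), showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  entries <- list()
  truth <- data.frame(left_id = character(0), right_id = character(0))
  for (g in config$groups) {
    nTotal <- config$nPaired + config$nUnpairedLeft
    for (i in seq_len(nTotal)) {
      id <- sprintf("%s%02d", g, i)
      sd <- .spawnSeed(config$seed, g, i)
      ind <- generateIndividual(sd, config, id = id)
      paired <- i <= config$nPaired
      sides <- if (paired) c("L", "R") else "L"
      files <- character(0)
      for (s in sides) {
        mesh <- if (s == "L") ind$left else ind$right
        lm <- if (s == "L") ind$leftLm else ind$rightLm
        mf <- file.path(outDir, "meshes", sprintf("%s_%s.stl", id, s))
        lf <- file.path(outDir, "landmarks", sprintf("%s_%s.json", id, s))
        writeMesh(mesh, mf, format = "stl_binary")
        writeLandmarks(lm, lf)
        files <- c(files, mf, lf)
      }
      if (paired)
        truth <- rbind(truth, data.frame(left_id = paste0(id, "_L"),
                                         right_id = paste0(id, "_R")))
      entries[[id]] <- list(id = id, group = g, seed = sd, paired = paired,
                            files = basename(files))
    }
  }
  utils::write.csv(truth, file.path(outDir, "truth.csv"), row.names = FALSE)
  allFiles <- c(list.files(file.path(outDir, "meshes"), full.names = TRUE),
                list.files(file.path(outDir, "landmarks"), full.names = TRUE))
  checksums <- as.list(tools::md5sum(sort(allFiles)))
  names(checksums) <- basename(names(checksums))
  manifest <- list(config = config, individuals = unname(entries),
                   checksums = checksums)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
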