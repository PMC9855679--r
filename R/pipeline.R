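.readAssemblage <- function(assemblageDir) {
  mpath <- file.path(assemblageDir, "manifest.json")
  if (!file.exists(mpath))
    stop("no manifest.json in assemblage directory: ", assemblageDir)
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = FALSE)
  inds <- manifest$individuals
  if (length(inds) == 0L) stop("assemblage is empty")
  meshes <- list()
  lms <- list()
  for (ind in inds) {
    sides <- if (isTRUE(ind$paired)) c("L", "R") else "L"
    for (s in sides) {
      mid <- sprintf("%s_%s", ind$id, s)
      mf <- file.path(assemblageDir, "meshes", paste0(mid, ".stl"))
      lf <- file.path(assemblageDir, "landmarks", paste0(mid, ".json"))
      meshes[[mid]] <- readMesh(mf, id = mid,
                                side = if (s == "L") "left" else "right")
      lms[[mid]] <- if (file.exists(lf)) readLandmarks(lf) else NULL
    }
  }
  truth <- utils::read.csv(file.path(assemblageDir, "truth.csv"),
                           colClasses = "character")
  groups <- vapply(inds, function(x) x$group, character(1))
  ids <- vapply(inds, function(x) x$id, character(1))
  paired <- vapply(inds, function(x) isTRUE(x$paired), logical(1))
  list(manifest = manifest, meshes = meshes, landmarks = lms, truth = truth,
       ids = ids, groups = groups, paired = paired)
}

.superimposePair <- function(asm, leftId, rightId, params, plane, log = NULL,
                             lmOverride = NULL) {
  lmL <- if (!is.null(lmOverride)) lmOverride[[leftId]]
         else asm$landmarks[[leftId]]
  lmR <- if (!is.null(lmOverride)) lmOverride[[rightId]]
         else asm$landmarks[[rightId]]
  if (is.null(lmL) || is.null(lmR))
    stop("missing landmarks for pair (", leftId, ", ", rightId, ")")
  moving <- mirrorMesh(asm$meshes[[leftId]], plane)
  movingLm <- mirrorLandmarks(lmL, plane)
  res <- superimpose(moving, asm$meshes[[rightId]], movingLm, lmR,
                     params = params)
  if (!is.null(log)) {
    cat(sprintf("%s[%s x %s] iterations=%d converged=%s rms=%.6f mm\n",
                if (res$registration@converged) "" else "WARN non-converged ",
                leftId, rightId, res$registration@iterations,
                res$registration@converged, res$rms), file = log,
        append = TRUE)
  }
  list(rms = res$rms, converged = res$registration@converged,
       iterations = res$registration@iterations)
}

#' Run the full pair-matching pipeline on an assemblage
#'
#' For every (left, right) model combination within each group: mirror the
#' left model, align by the three landmarks, refine by ICP and record the
#' RMS point-to-surface distance. Per group (and, with `pooled = TRUE`, for
#' the union of all groups' comparisons) it assembles the
#' [ComparisonMatrix-class], sweeps thresholds, classifies at the given or
#' sweep-recommended threshold and runs the match-vs-mismatch rank-sum
#' test. Comparisons are never made across groups — group membership (the
#' analogue of a prior sex assessment) restricts the comparison space.
#'
#' Non-converged registrations are retained in the matrix and flagged in
#' the log, not dropped. A pair whose landmark file is missing is logged as
#' failed and skipped; its cell stays empty.
#'
#' @param assemblageDir directory produced by [generateAssemblage()] (or
#'   laid out the same way).
#' @param outDir if non-`NULL`, writes `matrix_<group>.csv`, `sweep.json`,
#'   `classification.json`, `ranksum.json` and `run.log` there.
#' @param params [icpParams()].
#' @param plane mirror plane (default `"x"`).
#' @param thresholdMM fixed classification threshold; `NULL` (default) uses
#'   each group's sweep recommendation.
#' @param pooled also compute the combined (all groups) report (default
#'   `TRUE`).
#' @return List with one entry per group (each holding `matrix`, `sweep`,
#'   `classification`, `ranksum`) plus `combined` when `pooled`.
#' @export
runPipeline <- function(assemblageDir, outDir = NULL, params = icpParams(),
                        plane = "x", thresholdMM = NULL, pooled = TRUE) {
  asm <- .readAssemblage(assemblageDir)
  log <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(outDir, "run.log")
    cat("", file = log)
  }
  allRows <- list()
  for (g in unique(asm$groups)) {
    gids <- asm$ids[asm$groups == g]
    leftIds <- paste0(gids, "_L")
    rightIds <- paste0(gids[asm$paired[asm$groups == g]], "_R")
    for (l in leftIds) for (r in rightIds) {
      row <- tryCatch({
        s <- .superimposePair(asm, l, r, params, plane, log)
        data.frame(group = g, left_id = l, right_id = r, rms_mm = s$rms,
                   converged = s$converged, iterations = s$iterations)
      }, error = function(e) {
        if (!is.null(log))
          cat(sprintf("ERROR [%s x %s] %s\n", l, r, conditionMessage(e)),
              file = log, append = TRUE)
        NULL
      })
      if (!is.null(row)) allRows[[length(allRows) + 1L]] <- row
    }
  }
  if (length(allRows) == 0L) stop("no comparisons could be performed")
  cells <- do.call(rbind, allRows)
  out <- list()
  analyse <- function(sub, truthSub, label) {
    mat <- buildComparisonMatrix(sub, truthSub, group = label)
    sw <- sweepThresholds(mat)
    thr <- if (is.null(thresholdMM)) sw$recommended_threshold_mm
           else thresholdMM
    rs <- if (nMatches(mat) > 0 && nMismatches(mat) > 0)
      rankSumTest(matchRMS(mat), mismatchRMS(mat)) else NULL
    list(matrix = mat, sweep = sw, classification = classify(mat, thr),
         ranksum = rs, cells = sub)
  }
  for (g in unique(asm$groups)) {
    sub <- cells[cells$group == g, ]
    truthSub <- asm$truth[asm$truth$left_id %in% sub$left_id, ]
    out[[g]] <- analyse(sub, truthSub, g)
  }
  if (pooled && length(unique(asm$groups)) > 1L)
    out$combined <- analyse(cells, asm$truth, "combined")
  if (!is.null(outDir)) .writePipelineOutputs(out, outDir)
  out
}

.writePipelineOutputs <- function(out, outDir) {
  reports <- list()
  sweeps <- list()
  ranksums <- list()
  for (g in names(out)) {
    writeComparisonMatrix(out[[g]]$matrix,
                          file.path(outDir, sprintf("matrix_%s.csv", g)))
    r <- out[[g]]$classification
    reports[[g]] <- list(threshold_mm = r@thresholdMM, tp = r@tp, fp = r@fp,
                         tn = r@tn, fn = r@fn,
                         sensitivity_pct = r@sensitivity,
                         specificity_pct = r@specificity)
    sweeps[[g]] <- list(
      recommended_threshold_mm = out[[g]]$sweep$recommended_threshold_mm,
      sweep = out[[g]]$sweep$sweep)
    ranksums[[g]] <- out[[g]]$ranksum
  }
  jsonlite::write_json(reports, file.path(outDir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(sweeps, file.path(outDir, "sweep.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(ranksums, file.path(outDir, "ranksum.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Repeatability protocol: repeated runs with landmark jitter
#'
#' Landmark placement is the only manual step of the protocol, so operator
#' variation is simulated as Gaussian jitter of the landmark coordinates.
#' The superimposition of the first `nSubjects` paired individuals (their
#' matches and all within-group mismatches among them) is executed `runs`
#' times with independently jittered landmarks, and TEM / rTEM are reported
#' separately over match RMS values and mismatch RMS values (between the
#' first two runs when `runs = 2`; consecutive run pairs are pooled for
#' `runs > 2`).
#'
#' @param assemblageDir directory from [generateAssemblage()].
#' @param nSubjects number of paired subjects to use (default 10).
#' @param runs number of repeated runs (>= 2; default 2).
#' @param jitterSD landmark jitter standard deviation in mm (default 0.5;
#'   0 gives TEM = 0 since the pipeline is deterministic).
#' @param seed seed for the jitter draws.
#' @param params [icpParams()].
#' @param plane mirror plane.
#' @return List with `matches` and `mismatches`
#'   ([RepeatabilityReport-class]) and the per-run RMS tables.
#' @export
repeatabilityProtocol <- function(assemblageDir, nSubjects = 10, runs = 2,
                                  jitterSD = 0.5, seed = 1,
                                  params = icpParams(), plane = "x") {
  if (runs < 2) stop("runs must be >= 2")
  asm <- .readAssemblage(assemblageDir)
  pairedIds <- asm$ids[asm$paired]
  if (nSubjects > length(pairedIds))
    stop(sprintf("assemblage has only %d paired subjects (%d requested)",
                 length(pairedIds), nSubjects))
  use <- pairedIds[seq_len(nSubjects)]
  useGroups <- asm$groups[asm$paired][seq_len(nSubjects)]
  combos <- do.call(rbind, lapply(seq_along(use), function(i) {
    sameGroup <- use[useGroups == useGroups[i]]
    data.frame(left_id = paste0(use[i], "_L"),
               right_id = paste0(sameGroup, "_R"),
               match = sameGroup == use[i])
  }))
  runRMS <- matrix(NA_real_, nrow(combos), runs)
  set.seed(as.integer(seed))
  for (k in seq_len(runs)) {
    jittered <- lapply(asm$landmarks, function(lm) {
      if (is.null(lm)) return(NULL)
      lm@points <- lm@points + matrix(stats::rnorm(9, 0, jitterSD), 3, 3)
      lm
    })
    names(jittered) <- names(asm$landmarks)
    for (i in seq_len(nrow(combos))) {
      runRMS[i, k] <- .superimposePair(asm, combos$left_id[i],
                                       combos$right_id[i], params, plane,
                                       lmOverride = jittered)$rms
    }
  }
  pairTem <- function(sel, mode) {
    r1 <- as.numeric(runRMS[sel, seq_len(runs - 1L)])
    r2 <- as.numeric(runRMS[sel, 1L + seq_len(runs - 1L)])
    tem(r1, r2, mode = mode)
  }
  list(matches = pairTem(combos$match, "intra"),
       mismatches = pairTem(!combos$match, "intra"),
       rms = cbind(combos, runRMS))
}
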