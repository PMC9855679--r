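#' Assemble an all-against-all comparison matrix
#'
#' Arranges superimposition results into a left-by-right grid with ground
#' truth. Cells absent from `superimpositions` (e.g. cross-group
#' combinations in a pooled design) stay `NA` and are excluded from all
#' counts; duplicate cells and truth pairs without a cell are errors.
#'
#' The study design this supports: per sex group, 20 paired individuals
#' plus 2 extra unpaired left models give a 22 x 20 grid of 440
#' superimpositions — 20 matches and 420 mismatches; pooling both sexes
#' gives 880 cells, 40 matches, 840 mismatches.
#'
#' @param superimpositions data.frame with columns `left_id`, `right_id`,
#'   `rms_mm` (one row per superimposition).
#' @param truth data.frame (or 2-column matrix) of true pairs with columns
#'   `left_id`, `right_id`.
#' @param group label (default `"combined"`).
#' @return A validated [ComparisonMatrix-class].
#' @export
buildComparisonMatrix <- function(superimpositions, truth,
                                  group = "combined") {
  s <- as.data.frame(superimpositions)
  if (!all(c("left_id", "right_id", "rms_mm") %in% names(s)))
    stop("superimpositions needs columns left_id, right_id, rms_mm")
  key <- paste(s$left_id, s$right_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate superimposition cell(s): ",
         paste(unique(sub("\r", " x ", key[duplicated(key)])),
               collapse = ", "))
  left <- unique(as.character(s$left_id))
  right <- unique(as.character(s$right_id))
  m <- matrix(NA_real_, length(left), length(right),
              dimnames = list(left, right))
  m[cbind(match(s$left_id, left), match(s$right_id, right))] <- s$rms_mm
  tr <- as.matrix(as.data.frame(truth))[, 1:2, drop = FALSE]
  storage.mode(tr) <- "character"
  colnames(tr) <- c("left_id", "right_id")
  for (i in seq_len(nrow(tr))) {
    if (!tr[i, 1] %in% left || !tr[i, 2] %in% right ||
        is.na(m[tr[i, 1], tr[i, 2]]))
      stop(sprintf("truth pair (%s, %s) has no superimposition cell",
                   tr[i, 1], tr[i, 2]))
  }
  new("ComparisonMatrix", leftIds = left, rightIds = right, rms = m,
      truth = tr, group = group)
}

#' Number of compared cells / matches in a ComparisonMatrix
#'
#' @param x a [ComparisonMatrix-class].
#' @return Integer count.
#' @export
nCells <- function(x) sum(!is.na(x@rms))

#' @rdname nCells
#' @export
nMatches <- function(x) nrow(x@truth)

#' @rdname nCells
#' @export
nMismatches <- function(x) nCells(x) - nMatches(x)

#' RMS values of the true pairs / of the non-pairs
#'
#' @param x a [ComparisonMatrix-class].
#' @return Numeric vector of RMS values (mm).
#' @export
matchRMS <- function(x) {
  if (nrow(x@truth) == 0L) return(numeric(0))
  x@rms[cbind(match(x@truth[, 1], x@leftIds),
              match(x@truth[, 2], x@rightIds))]
}

#' @rdname matchRMS
#' @export
mismatchRMS <- function(x) {
  m <- x@rms
  if (nrow(x@truth))
    m[cbind(match(x@truth[, 1], x@leftIds),
            match(x@truth[, 2], x@rightIds))] <- NA
  as.numeric(m[!is.na(m)])
}

#' Classify every comparison against an RMS threshold
#'
#' A cell is predicted a match iff its RMS is less than or equal to the
#' threshold. The rule is inclusive: a true pair sitting exactly at the
#' threshold counts as detected, so a threshold placed at the largest match
#' RMS yields 100% sensitivity. On degenerate matrices (no truth pairs, or
#' no mismatch cells) the undefined rate is reported as `NA`; the stricter
#' [confusionStats()] treats those cases as errors.
#'
#' @param matrix a [ComparisonMatrix-class].
#' @param thresholdMM RMS cut-off in mm (> 0).
#' @return A [ClassificationReport-class].
#' @export
classify <- function(matrix, thresholdMM) {
  validObject(matrix)
  if (!is.numeric(thresholdMM) || length(thresholdMM) != 1L ||
      thresholdMM <= 0)
    stop("thresholdMM must be a single positive value")
  mrms <- matchRMS(matrix)
  xrms <- mismatchRMS(matrix)
  tp <- sum(mrms <= thresholdMM)
  fn <- length(mrms) - tp
  fp <- sum(xrms <= thresholdMM)
  tn <- length(xrms) - fp
  # degenerate matrices (no truth pairs, or no mismatches at all) leave the
  # corresponding rate undefined rather than failing the whole run
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  new("ClassificationReport", thresholdMM = thresholdMM,
      tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
      fn = as.integer(fn), sensitivity = sens, specificity = spec)
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity is the percentage of true pairs correctly identified as
#' matches, `100 tp / (tp + fn)`; specificity the percentage of non-pairs
#' correctly identified as mismatches, `100 tn / (tn + fp)`. Raw values are
#' returned alongside the one-decimal rounding used for reporting.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return List with `sensitivity_pct`, `specificity_pct` (raw) and
#'   `sensitivity_reported`, `specificity_reported` (rounded to 1 decimal).
#' @examples
#' confusionStats(20, 1, 419, 0)  # 100.0 / 99.8
#' @export
confusionStats <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (tp + fn == 0)
    stop("sensitivity undefined: no true pairs (tp + fn = 0)")
  if (tn + fp == 0)
    stop("specificity undefined: no non-pairs (tn + fp = 0)")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  list(sensitivity_pct = sens, specificity_pct = spec,
       sensitivity_reported = round(sens, 1),
       specificity_reported = round(spec, 1))
}

#' Sweep all candidate thresholds
#'
#' Evaluates the classification at every unique RMS value in the matrix
#' (each is a candidate inclusive threshold) and recommends one: among
#' thresholds with zero false negatives, the one with the fewest false
#' positives — ties broken towards the largest threshold. Because the rule
#' is inclusive, the smallest zero-miss threshold is the largest match RMS,
#' so the recommendation reproduces a cut-off placed at the top of the
#' match range.
#'
#' @param matrix a [ComparisonMatrix-class].
#' @return List with `sweep` (data.frame: `threshold_mm`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity_pct`, `specificity_pct`), `recommended_threshold_mm`
#'   and `report` (the [ClassificationReport-class] at the recommendation).
#' @export
sweepThresholds <- function(matrix) {
  validObject(matrix)
  thresholds <- sort(unique(as.numeric(matrix@rms[!is.na(matrix@rms)])))
  rows <- lapply(thresholds, function(t) {
    r <- classify(matrix, t)
    data.frame(threshold_mm = t, tp = r@tp, fp = r@fp, tn = r@tn, fn = r@fn,
               sensitivity_pct = r@sensitivity,
               specificity_pct = r@specificity)
  })
  sweep <- do.call(rbind, rows)
  ok <- sweep[sweep$fn == 0, , drop = FALSE]
  ok <- ok[ok$fp == min(ok$fp), , drop = FALSE]
  rec <- max(ok$threshold_mm)
  list(sweep = sweep, recommended_threshold_mm = rec,
       report = classify(matrix, rec))
}

#' Mann-Whitney rank-sum test of match vs mismatch RMS
#'
#' Tests whether the RMS distances of true pairs are distributed
#' differently from (in practice, lower than) those of non-pairs. Exact
#' two-sided p-value when the combined sample size is at most 20 and there
#' are no ties; normal approximation with continuity and tie correction
#' otherwise (via [stats::wilcox.test()]).
#'
#' @param matchRms,mismatchRms non-empty numeric vectors of RMS values (mm).
#' @return List with `U` (the Mann-Whitney statistic counting
#'   match-above-mismatch pairs), `p_two_sided` and `method`.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1 exactly
#' @export
rankSumTest <- function(matchRms, mismatchRms) {
  if (length(matchRms) == 0L || length(mismatchRms) == 0L)
    stop("both samples must be non-empty")
  n <- length(matchRms) + length(mismatchRms)
  ties <- anyDuplicated(c(matchRms, mismatchRms)) > 0
  exact <- n <= 20 && !ties
  wt <- stats::wilcox.test(matchRms, mismatchRms, exact = exact,
                           correct = TRUE)
  list(U = unname(wt$statistic), p_two_sided = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Technical error of measurement between two runs
#'
#' `TEM = sqrt(sum((run1 - run2)^2) / (2 n))`, the standard anthropometric
#' repeatability statistic; `rTEM` expresses it as a percentage of the
#' grand mean of all measurements from both runs. TEM is symmetric in the
#' runs and scales linearly with the measurements, which leaves rTEM
#' scale-free.
#'
#' @param run1,run2 equal-length numeric vectors of repeated measurements
#'   (mm).
#' @param mode `"intra"` or `"inter"` observer (annotation only).
#' @return A [RepeatabilityReport-class].
#' @examples
#' tem(1.0, 1.1)  # TEM sqrt(0.01 / 2) = 0.0707 mm, rTEM 6.73%
#' @export
tem <- function(run1, run2, mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  if (length(run1) != length(run2))
    stop("run1 and run2 must have equal length")
  if (length(run1) < 1L) stop("at least one measurement pair is required")
  temMM <- sqrt(sum((run1 - run2)^2) / (2 * length(run1)))
  gm <- mean(c(run1, run2))
  if (gm == 0) stop("rTEM undefined: grand mean of measurements is 0")
  new("RepeatabilityReport", temMM = temMM, rtemPercent = 100 * temMM / gm,
      nPairs = length(run1), mode = mode)
}

#' Write / read a ComparisonMatrix as CSV
#'
#' The matrix CSV has a header row of right ids and one row per left id;
#' the truth pairs go to a sidecar CSV with columns `left_id`, `right_id`.
#'
#' @param matrix a [ComparisonMatrix-class].
#' @param path matrix CSV path.
#' @param truthPath sidecar truth CSV path (default `<path>_truth.csv`
#'   next to `path`); `NULL` to skip.
#' @return Invisibly, `path`.
#' @export
writeComparisonMatrix <- function(matrix, path, truthPath = NULL) {
  validObject(matrix)
  df <- as.data.frame(matrix@rms)
  utils::write.csv(cbind(left_id = matrix@leftIds, df), path,
                   row.names = FALSE)
  if (is.null(truthPath))
    truthPath <- file.path(dirname(path),
                           paste0(tools::file_path_sans_ext(basename(path)),
                                  "_truth.csv"))
  utils::write.csv(as.data.frame(matrix@truth), truthPath, row.names = FALSE)
  invisible(path)
}

#' @rdname writeComparisonMatrix
#' @param group group label for the reconstructed object.
#' @export
readComparisonMatrix <- function(path, truthPath = NULL,
                                 group = "combined") {
  if (is.null(truthPath))
    truthPath <- file.path(dirname(path),
                           paste0(tools::file_path_sans_ext(basename(path)),
                                  "_truth.csv"))
  tab <- utils::read.csv(path, check.names = FALSE)
  left <- as.character(tab$left_id)
  m <- as.matrix(tab[, -1, drop = FALSE])
  long <- data.frame(left_id = rep(left, ncol(m)),
                     right_id = rep(colnames(m), each = nrow(m)),
                     rms_mm = as.numeric(m))
  long <- long[!is.na(long$rms_mm), ]
  truth <- utils::read.csv(truthPath, colClasses = "character")
  buildComparisonMatrix(long, truth, group = group)
}
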