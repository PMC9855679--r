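# Synthetic comparison designs used across these tests.
design_cells <- function(groups, nPaired = 20, nUnpairedLeft = 2,
                         seed = 1) {
  set.seed(seed)
  cells <- NULL
  truth <- NULL
  for (g in groups) {
    lefts <- sprintf("%s%02d_L", g, seq_len(nPaired + nUnpairedLeft))
    rights <- sprintf("%s%02d_R", g, seq_len(nPaired))
    grid <- expand.grid(left_id = lefts, right_id = rights,
                        stringsAsFactors = FALSE)
    is_match <- sub("_L", "", grid$left_id) == sub("_R", "", grid$right_id)
    grid$rms_mm <- ifelse(is_match, runif(nrow(grid), 0.4, 0.9),
                          runif(nrow(grid), 1.0, 5.6))
    cells <- rbind(cells, grid)
    truth <- rbind(truth, data.frame(left_id = sprintf("%s%02d_L", g,
                                                       seq_len(nPaired)),
                                     right_id = sprintf("%s%02d_R", g,
                                                        seq_len(nPaired))))
  }
  list(cells = cells, truth = truth)
}

test_that("the per-sex and pooled comparison designs count out correctly", {
  one <- design_cells("m")
  m1 <- buildComparisonMatrix(one$cells, one$truth, group = "males")
  expect_identical(nCells(m1), 440L)
  expect_identical(nMatches(m1), 20L)
  expect_identical(nMismatches(m1), 420L)

  both <- design_cells(c("m", "f"))
  m2 <- buildComparisonMatrix(both$cells, both$truth, group = "combined")
  expect_identical(nCells(m2), 880L)
  expect_identical(nMatches(m2), 40L)
  expect_identical(nMismatches(m2), 840L)

  tinyCells <- data.frame(left_id = "a_L", right_id = "a_R", rms_mm = 0.5)
  tinyTruth <- data.frame(left_id = "a_L", right_id = "a_R")
  m3 <- buildComparisonMatrix(tinyCells, tinyTruth)
  expect_identical(c(nCells(m3), nMatches(m3), nMismatches(m3)),
                   c(1L, 1L, 0L))
})

test_that("malformed comparison inputs are rejected", {
  cells <- data.frame(left_id = c("a_L", "a_L"), right_id = c("a_R", "a_R"),
                      rms_mm = c(0.5, 0.6))
  expect_error(buildComparisonMatrix(cells,
                                     data.frame(left_id = "a_L",
                                                right_id = "a_R")),
               "duplicate")
  cells2 <- data.frame(left_id = "a_L", right_id = "a_R", rms_mm = 0.5)
  expect_error(buildComparisonMatrix(cells2,
                                     data.frame(left_id = "b_L",
                                                right_id = "b_R")),
               "no superimposition cell")
  expect_error(buildComparisonMatrix(
    data.frame(left_id = c("a_L", "b_L"), right_id = c("a_R", "b_R"),
               rms_mm = c(0.5, -1)),
    data.frame(left_id = "a_L", right_id = "a_R")))
})

test_that("the inclusive threshold rule counts boundary matches as detected", {
  cells <- data.frame(
    left_id = c("a_L", "a_L", "b_L", "b_L"),
    right_id = c("a_R", "b_R", "a_R", "b_R"),
    rms_mm = c(0.41, 2.0, 0.87, 0.91))  # match b at exactly the threshold
  truth <- data.frame(left_id = c("a_L", "b_L"),
                      right_id = c("a_R", "b_R"))
  mat <- buildComparisonMatrix(cells, truth)
  rep <- classify(mat, 0.91)
  expect_identical(rep@fn, 0L)
  expect_identical(rep@tp, 2L)
  expect_equal(rep@sensitivity, 100)
  expect_identical(rep@fp, 1L)  # the 0.87 mm mismatch slips under the cut

  below <- classify(mat, 0.40)  # below the global minimum
  expect_identical(c(below@tp, below@fp), c(0L, 0L))
  expect_equal(below@specificity, 100)
})

test_that("confusion statistics reproduce closed-form rates and guard zeros", {
  r <- confusionStats(20, 1, 419, 0)
  expect_equal(r$sensitivity_reported, 100.0)
  expect_equal(r$specificity_reported, 99.8)
  expect_equal(r$specificity_pct, 100 * 419 / 420)
  expect_error(confusionStats(0, 0, 10, 0), "sensitivity undefined")
  expect_error(confusionStats(5, 0, 0, 0), "specificity undefined")
  expect_error(confusionStats(-1, 0, 1, 1), "non-negative")
})

test_that("the threshold sweep recommends the largest zero-miss cut-off", {
  d <- design_cells("m", seed = 3)
  mat <- buildComparisonMatrix(d$cells, d$truth, group = "males")
  sw <- sweepThresholds(mat)
  expect_equal(sw$recommended_threshold_mm, max(matchRMS(mat)))
  # idempotence: re-applying classify at the recommendation reproduces it
  again <- classify(mat, sw$recommended_threshold_mm)
  expect_identical(again@tp, sw$report@tp)
  expect_identical(again@fp, sw$report@fp)
  expect_identical(sw$report@fn, 0L)
  # monotone: sensitivity non-decreasing, specificity non-increasing
  expect_true(all(diff(sw$sweep$sensitivity_pct) >= 0))
  expect_true(all(diff(sw$sweep$specificity_pct) <= 0))
  # confusion counts always total the cell count
  expect_true(all(rowSums(sw$sweep[, c("tp", "fp", "tn", "fn")]) ==
                    nCells(mat)))
  # separated data: some threshold reaches 100/100
  expect_true(any(sw$sweep$sensitivity_pct == 100 &
                    sw$sweep$specificity_pct == 100))
})

test_that("an all-equal matrix classifies everything as a match", {
  cells <- data.frame(left_id = rep(c("a_L", "b_L"), each = 2),
                      right_id = rep(c("a_R", "b_R"), 2),
                      rms_mm = rep(1.5, 4))
  truth <- data.frame(left_id = c("a_L", "b_L"),
                      right_id = c("a_R", "b_R"))
  sw <- sweepThresholds(buildComparisonMatrix(cells, truth))
  expect_identical(nrow(sw$sweep), 1L)
  expect_equal(sw$sweep$sensitivity_pct, 100)
  expect_equal(sw$sweep$specificity_pct, 0)
})

test_that("rank-sum test matches exact enumeration and handles edge cases", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_identical(unname(r$U), 0)
  expect_equal(r$p_two_sided, 0.1, tolerance = 1e-12)

  same <- rankSumTest(c(1, 2), c(1, 2))
  expect_gte(same$p_two_sided, 0.99)

  set.seed(17)
  for (rep in 1:10) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- sample(seq(0.1, 9.9, 0.1), n1)
    y <- sample(setdiff(seq(0.1, 9.9, 0.1), x), n2)
    got <- rankSumTest(x, y)
    expect_equal(got$p_two_sided, oracle_exact_ranksum_p(x, y),
                 tolerance = 1e-9)
  }
  expect_error(rankSumTest(numeric(0), 1), "non-empty")
})

test_that("comparison matrices round-trip through CSV", {
  dir <- withr::local_tempdir()
  d <- design_cells("f", nPaired = 4, nUnpairedLeft = 1, seed = 6)
  mat <- buildComparisonMatrix(d$cells, d$truth, group = "females")
  p <- file.path(dir, "matrix.csv")
  writeComparisonMatrix(mat, p)
  back <- readComparisonMatrix(p, group = "females")
  expect_identical(nCells(back), nCells(mat))
  expect_equal(sort(matchRMS(back)), sort(matchRMS(mat)), tolerance = 1e-9)
  expect_equal(sort(mismatchRMS(back)), sort(mismatchRMS(mat)),
               tolerance = 1e-9)
})

test_that("TEM and rTEM follow their closed forms and invariances", {
  zero <- tem(c(1, 2, 3), c(1, 2, 3))
  expect_identical(zero@temMM, 0)
  expect_identical(zero@rtemPercent, 0)

  single <- tem(1.0, 1.1)
  expect_equal(single@temMM, sqrt(0.01 / 2), tolerance = 1e-9)
  expect_equal(single@rtemPercent, 100 * sqrt(0.01 / 2) / 1.05,
               tolerance = 1e-4)

  pairs <- tem(c(0.70, 0.50), c(0.73, 0.47))
  expect_equal(pairs@temMM, sqrt((0.0009 + 0.0009) / 4), tolerance = 1e-9)

  set.seed(4)
  a <- runif(8, 0.4, 2)
  b <- a + rnorm(8, 0, 0.05)
  expect_equal(tem(a, b)@temMM, tem(b, a)@temMM, tolerance = 1e-12)
  scaled <- tem(3 * a, 3 * b)
  expect_equal(scaled@temMM, 3 * tem(a, b)@temMM, tolerance = 1e-12)
  expect_equal(scaled@rtemPercent, tem(a, b)@rtemPercent, tolerance = 1e-12)

  expect_error(tem(1:3, 1:2), "equal length")
  expect_error(tem(c(-1, 1), c(1, -1)), "grand mean")
})
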