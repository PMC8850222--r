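test_that("reports count correct, over- and under-predictions with signed deviations", {
  r <- build_report(3, 1)
  expect_equal(r$n_over, 1)
  expect_equal(r$n_correct, 0)
  expect_equal(unname(r$deviation_histogram[["2"]]), 1)
  same <- build_report(c(1, 3, 5), c(1, 3, 5))
  expect_equal(same$n_correct, 3)
  expect_equal(same$n_over + same$n_under, 0)
  under <- build_report(2, 5)
  expect_equal(under$n_under, 1)
  expect_equal(unname(under$deviation_histogram[["-3"]]), 1)
  expect_error(build_report(1:3, 1:2), "equal length")
  expect_error(build_report(c(1, 6), c(1, 2)), "1..5")
})

test_that("reports are invariant to the ordering of compound pairs", {
  set.seed(61)
  e <- sample(1:5, 40, replace = TRUE)
  p <- sample(1:5, 40, replace = TRUE)
  perm <- sample(40)
  r1 <- build_report(e, p)
  r2 <- build_report(e[perm], p[perm])
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$deviation_histogram, r2$deviation_histogram)
})

test_that("overprediction counting matches the published Tier-0 confusion matrix", {
  tier0 <- rbind(c(6, 0, 0, 0, 0),
                 c(14, 0, 0, 0, 0),
                 c(10, 0, 0, 0, 0),
                 c(9, 0, 1, 0, 0),
                 c(7, 0, 3, 0, 0))
  expect_equal(count_overpredictions(tier0), 44)
  expect_equal(count_underpredictions(tier0), 0)
  expect_equal(count_overpredictions(diag(c(3, 4, 5, 6, 7))), 0)
  corner <- matrix(0, 5, 5); corner[1, 5] <- 9
  expect_equal(count_overpredictions(corner), 0)
  expect_equal(count_underpredictions(corner), 9)
})

test_that("over + under + diagonal exhausts any confusion matrix", {
  set.seed(62)
  for (i in 1:20) {
    m <- matrix(rpois(25, 3), 5, 5)
    expect_equal(count_overpredictions(m) + count_underpredictions(m) +
                   sum(diag(m)), sum(m))
  }
})

test_that("report totals reconcile with the confusion matrix", {
  set.seed(63)
  e <- sample(1:5, 60, replace = TRUE)
  p <- sample(1:5, 60, replace = TRUE)
  r <- build_report(e, p)
  expect_equal(r$n_over, count_overpredictions(r$confusion))
  expect_equal(r$n_under, count_underpredictions(r$confusion))
  expect_equal(r$n_correct + r$n_over + r$n_under, 60)
  expect_equal(sum(r$deviation_histogram), 60)
  expect_equal(unname(r$deviation_histogram[["0"]]), r$n_correct)
})

test_that("the LD50 variability switch recategorizes shifted values", {
  rec <- function(ld) as_compound_records(data.frame(
    compound_id = paste0("v", seq_along(ld)), smiles = "CCO",
    ld50_mg_kg = ld, stringsAsFactors = FALSE))
  z <- ld50_variability_switch(rec(c(10, 100, 1000)), delta = 0)
  expect_equal(z$pct_changed_up, 0)
  expect_equal(z$pct_changed_down, 0)
  # 1900 mg/kg times 10^0.31 is about 3879: category 4 -> 5
  one <- ld50_variability_switch(rec(1900), delta = 0.31)
  expect_equal(one$pct_changed_up, 100)
  # 100 mg/kg shifts to about 204, still inside category 3
  two <- ld50_variability_switch(rec(100), delta = 0.31)
  expect_equal(two$pct_changed_up, 0)
  expect_error(ld50_variability_switch(rec(10), delta = -1), "non-negative")
})

test_that("switch percentages grow with the shift magnitude", {
  set.seed(64)
  rec <- as_compound_records(data.frame(
    compound_id = sprintf("m%03d", 1:150), smiles = "CCO",
    ld50_mg_kg = 10^runif(150, -0.5, 4), stringsAsFactors = FALSE))
  deltas <- c(0, 0.1, 0.31, 0.6, 1)
  ups <- vapply(deltas, function(d)
    ld50_variability_switch(rec, d)$pct_changed_up, numeric(1))
  downs <- vapply(deltas, function(d)
    ld50_variability_switch(rec, d)$pct_changed_down, numeric(1))
  expect_true(all(diff(ups) >= 0))
  expect_true(all(diff(downs) >= 0))
})

test_that("reports serialize to confusion and summary files", {
  r <- build_report(c(1, 2, 3, 4, 5, 3), c(1, 1, 3, 5, 5, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(r, path)
  expect_true(file.exists(path))
  summary_path <- sub("\\.csv$", "_summary.txt", path)
  lines <- readLines(summary_path)
  expect_true(any(grepl("correct=3", lines)))
  expect_true(any(grepl("overpredicted=2", lines)))
  expect_true(any(grepl("underpredicted=1", lines)))
})
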