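test_that("categorize maps LD50 onto the CLP-style bands with half-open edges", {
  b <- category_bounds()
  cases <- list(c(4, 1), c(2000, 5), c(50, 3), c(5, 2),
                c(0.01, 1), c(4.999, 1), c(49.9, 2), c(299.9, 3),
                c(300, 4), c(1999.9, 4), c(1e6, 5))
  for (cs in cases) expect_identical(categorize(cs[1], b), as.integer(cs[2]))
  expect_identical(categorize(c(4, 2000, 50, 5)), c(1L, 5L, 3L, 2L))
  expect_error(categorize(-1), "positive")
  expect_error(categorize(0), "positive")
  expect_identical(categorize(NA_real_), NA_integer_)
})

test_that("categorize is monotone and returns the band of each interval midpoint", {
  set.seed(11)
  ld <- sort(10^runif(200, -2, 5))
  cat <- categorize(ld)
  expect_true(all(diff(cat) >= 0))
  edges <- c(0.1, 5, 50, 300, 2000, 10^4.7)
  mids <- (edges[-6] + edges[-1]) / 2
  expect_identical(categorize(mids), 1:5)
})

test_that("LD50 converts to log10 mmol/kg and responds monotonically", {
  expect_equal(to_log_mmol_kg(180, 180), 0)
  expect_equal(to_log_mmol_kg(5, 500), -2)
  expect_equal(to_log_mmol_kg(2000, 200), 1)
  expect_error(to_log_mmol_kg(-5, 100), "positive")
  # strictly increasing in LD50, strictly decreasing in MW
  ld <- c(1, 10, 100); expect_true(all(diff(to_log_mmol_kg(ld, 100)) > 0))
  mw <- c(50, 100, 200); expect_true(all(diff(to_log_mmol_kg(100, mw)) < 0))
})

test_that("record validation enforces invariants and derives columns", {
  rec <- as_compound_records(make_record_df(4))
  expect_s3_class(rec, "compound_records")
  expect_identical(rec$experimental_category, categorize(rec$ld50_mg_kg))
  expect_equal(rec$log_ld50_mmol_kg, log10(rec$ld50_mg_kg / rec$mol_weight))
  bad <- make_record_df(3); bad$ld50_mg_kg[2] <- -4
  expect_error(as_compound_records(bad), "positive")
  dup <- make_record_df(3); dup$compound_id[2] <- dup$compound_id[1]
  expect_error(as_compound_records(dup), "duplicated")
  odd <- make_record_df(3); odd$cramer_class[1] <- "IV"
  expect_error(as_compound_records(odd), "Cramer")
})

test_that("compound tables read with exclusion of duplicates and bad structures", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(id = c("a", "b", "c"), smiles = c("CCO", "CCN", "CCC"),
                   mw = c(46.07, 45.08, 44.1), ld50_mg_kg = c(10, 100, 1000),
                   cramer_class = c("I", "II", "III"))
  write.csv(df, path, row.names = FALSE)
  rec <- read_compound_table(path)
  expect_equal(nrow(rec), 3)
  expect_identical(rec$experimental_category, c(2L, 3L, 4L))

  df2 <- df; df2$id[3] <- "a"
  write.csv(df2, path, row.names = FALSE)
  expect_message(rec2 <- read_compound_table(path), "1 duplicated")
  expect_equal(nrow(rec2), 2)
  expect_identical(attr(rec2, "n_excluded_duplicate"), 1L)

  df3 <- df; df3$smiles[2] <- "this(is(not(smiles"
  write.csv(df3, path, row.names = FALSE)
  expect_message(rec3 <- read_compound_table(path), "1 unparseable")
  expect_equal(nrow(rec3), 2)
  expect_identical(attr(rec3, "n_excluded_structure"), 1L)

  df4 <- df[, setdiff(names(df), "smiles")]
  write.csv(df4, path, row.names = FALSE)
  expect_error(read_compound_table(path), "smiles")
})

test_that("missing molecular weight is filled from the parsed structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "eth", smiles = "CCO", ld50_mg_kg = 7000),
            path, row.names = FALSE)
  rec <- read_compound_table(path)
  expect_equal(rec$mol_weight, 46.07, tolerance = 1e-3)
  expect_equal(rec$log_ld50_mmol_kg, log10(7000 / 46.06844), tolerance = 1e-4)
})

test_that("record tables round-trip through write_compound_table", {
  rec <- make_full_records(6)
  rec$alert_names[[2]] <- c("organophosphate", "carbamate")
  path <- withr::local_tempfile(fileext = ".csv")
  write_compound_table(rec, path)
  back <- read_compound_table(path)
  expect_equal(back$ld50_mg_kg, rec$ld50_mg_kg, tolerance = 1e-9)
  expect_identical(back$alert_names[[2]], c("organophosphate", "carbamate"))
  expect_identical(back$cramer_class, rec$cramer_class)
})
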