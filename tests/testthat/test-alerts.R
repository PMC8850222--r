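test_that("the rare-alert rule is 90/0/0/10/0 with its documented summaries", {
  d <- rare_alert_distribution()
  expect_equal(unname(d), c(0.90, 0, 0, 0.10, 0))
  expect_equal(expected_severity(d), 1.3)
  expect_identical(assign_category_exclusionary(d, 0.10), 1L)
})

test_that("the shipped alert table matches the published distributions", {
  tab <- default_alerts()
  expect_equal(nrow(tab), 13)
  probs <- as.matrix(tab[, paste0("cat", 1:5)])
  expect_equal(unname(rowSums(probs)), rep(1, 13), tolerance = 1e-12)
  published <- list(
    organophosphate = c(41.8, 33.9, 16.7, 4.6, 3.1),
    carbamate = c(31.5, 40.0, 16.4, 8.3, 4.2),
    fluoromethyl_benzimidazole = c(51.6, 41.3, 7.0, 0.0, 0.0),
    vitamin_k_antagonist = c(84.4, 5.8, 7.6, 2.2, 0.0),
    dibenzodioxin = c(96.3, 3.7, 0.0, 0.0, 0.0))
  coverage <- c(organophosphate = 730L, carbamate = 327L,
                fluoromethyl_benzimidazole = 128L,
                vitamin_k_antagonist = 11L, dibenzodioxin = 10L)
  for (nm in names(published)) {
    i <- match(nm, tab$name)
    expect_true(all(abs(100 * probs[i, ] - published[[nm]]) <= 0.2),
                label = nm)
    expect_identical(tab$coverage[i], coverage[[nm]])
    expect_false(tab$is_estimated[i])
  }
  rare <- tab[tab$is_estimated, ]
  expect_equal(nrow(rare), 8)
  for (i in seq_len(nrow(rare))) {
    expect_equal(as.numeric(rare[i, paste0("cat", 1:5)]),
                 unname(rare_alert_distribution()))
  }
})

test_that("substructure matching hits the intended chemistry and nothing else", {
  hits <- match_alerts(c(
    paraoxon = "O=P(OCC)(OCC)Oc1ccc(cc1)[N+](=O)[O-]",
    ethanol = "CCO",
    warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O"))
  expect_identical(hits[[1]], "organophosphate")
  expect_identical(hits[[2]], character(0))
  expect_identical(hits[[3]], "vitamin_k_antagonist")
  expect_false(any(attr(hits, "failed")))
})

test_that("every alert-bearing template matches exactly its own alert", {
  tm <- toxtiers:::synth_templates()
  hits <- match_alerts(tm$smiles)
  expected <- c(paraoxon = "organophosphate", carbaryl = "carbamate",
                warfarin = "vitamin_k_antagonist", tcdd = "dibenzodioxin",
                fenazaflor = "fluoromethyl_benzimidazole",
                pindone = "indandione")
  for (i in seq_len(nrow(tm))) {
    if (tm$has_alert[i]) {
      expect_identical(hits[[i]], unname(expected[tm$name[i]]),
                       label = tm$name[i])
    } else {
      expect_identical(hits[[i]], character(0), label = tm$name[i])
    }
  }
  # determinism: repeated query yields identical results
  expect_identical(hits, match_alerts(tm$smiles))
})

test_that("unparseable structures are flagged and return no matches", {
  hits <- match_alerts(c("CCO", "not(a(smiles"))
  expect_identical(attr(hits, "failed"), c(FALSE, TRUE))
  expect_identical(hits[[2]], character(0))
})

test_that("calculated alert distributions reuse the prevalence-scaling rule", {
  prev <- as.numeric(reference_prevalence())
  matches <- c(20, 5, 3, 1, 1)
  expect_equal(unname(derive_alert_distribution(matches)),
               oracle_scale(matches, prev), tolerance = 1e-12)
  expect_equal(unname(derive_alert_distribution(prev)), rep(0.2, 5),
               tolerance = 1e-12)
  expect_equal(unname(derive_alert_distribution(c(12, 0, 0, 0, 0))),
               c(1, 0, 0, 0, 0))
  expect_error(derive_alert_distribution(c(5, 2, 1, 0, 0)), "below 10")
  # exactly ten matching compounds uses the calculated route
  expect_silent(derive_alert_distribution(c(8, 1, 1, 0, 0)))
})

test_that("multi-alert compounds contribute their most severe alert distribution", {
  tab <- default_alerts()
  d <- alert_contribution(c("organophosphate", "dibenzodioxin"), tab)
  expect_equal(unname(d),
               unname(category_distribution(
                 as.numeric(tab[tab$name == "dibenzodioxin", paste0("cat", 1:5)]))),
               tolerance = 1e-12)
  expect_null(alert_contribution(character(0), tab))
  expect_error(alert_contribution("unheard_of", tab), "unknown")
})

test_that("alert tables survive a file round-trip", {
  tab <- default_alerts()
  path <- withr::local_tempfile(fileext = ".csv")
  out <- as.data.frame(tab)
  for (k in paste0("cat", 1:5)) out[[k]] <- 100 * out[[k]]
  write.csv(out, path, row.names = FALSE)
  back <- read_alert_table(path)
  expect_equal(back$smarts, tab$smarts)
  expect_equal(as.matrix(back[, paste0("cat", 1:5)]),
               as.matrix(tab[, paste0("cat", 1:5)]), tolerance = 1e-9)
  expect_identical(back$is_estimated, tab$is_estimated)
})
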