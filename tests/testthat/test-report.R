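test_that("the simulated table is valid, complete and device-correlated", {
  tab <- simulateStiffnessTable(seed = 4)
  expect_silent(validateStiffnessTable(tab))
  expect_equal(nrow(tab), 14 * 2 * 3 * 2)
  oct <- tab[tab$device == "oct", ]
  ref <- tab[tab$device == "reference", ]
  expect_gt(cor(oct$k_value, ref$k_value), 0.9)
  # wound stiffer than normal, lower wound stiffer than upper wound (in mean)
  m <- tapply(oct$k_value, list(oct$status, oct$location), mean)
  expect_gt(m["wound", "upper"], m["normal", "upper"])
  expect_gt(m["wound", "lower"], m["wound", "upper"])
})

test_that("table validation catches duplicates and bad values", {
  tab <- simulateStiffnessTable(seed = 4)
  expect_error(validateStiffnessTable(rbind(tab, tab[1, ])), "duplicate")
  bad <- tab
  bad$k_value[1] <- -1
  expect_error(validateStiffnessTable(bad), "positive")
  expect_error(validateStiffnessTable(tab[, -5]), "missing columns")
})

test_that("the report emits all six table layouts with significance flags", {
  tab <- simulateStiffnessTable(seed = 8)
  rep <- analysisReport(tab)
  expect_equal(nrow(rep$locationTTests), 6)   # 2 devices x 3 statuses
  expect_equal(nrow(rep$statusAnova), 4)      # 2 devices x 2 locations
  expect_equal(nrow(rep$icc), 2)
  expect_equal(nrow(rep$effectSizeStatus), 12)  # 2 x 2 x 3 pairs
  expect_equal(nrow(rep$effectSizeLocation), 6)
  expect_equal(nrow(rep$correlation), 6)
  expect_true(all(c("p_normal_vs_wound", "p_normal_vs_after",
                    "p_wound_vs_after") %in% names(rep$statusAnova)))
  expect_true(all(rep$correlation$sig == "**"))

  d <- withr::local_tempdir()
  writeReport(rep, d)
  expect_length(list.files(d, pattern = "\\.csv$"), 6L)
})

test_that("a single-status table skips the ANOVA sections with a warning", {
  tab <- simulateStiffnessTable(seed = 9)
  tab <- tab[tab$status == "wound", ]
  expect_warning(rep <- analysisReport(tab), "single status")
  expect_null(rep$statusAnova)
  expect_true(any(grepl("ANOVA", rep$skipped)))
})

test_that("missing cells are listed and their contrasts skipped, not imputed", {
  tab <- simulateStiffnessTable(seed = 10)
  # drop all but one subject from the oct/upper/wound cell
  drop <- tab$device == "oct" & tab$location == "upper" &
    tab$status == "wound" & tab$subject_id != "S01"
  rep <- analysisReport(tab[!drop, ])
  expect_true(any(grepl("oct/upper", rep$skipped)))
  expect_false(any(rep$statusAnova$device == "oct" &
                     rep$statusAnova$location == "upper"))
})
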