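srh_spec <- variable_spec("srh", "ordinal", "higher_is_better", "both_waves",
                          0, 4)
med_spec <- variable_spec("medications", "continuous", "higher_is_worse",
                          "both_waves", 0, 15)

test_that("change coding maps signs through the variable's direction", {
  expect_identical(as.character(code_change(srh_spec, 3, 2)), "worsened")
  expect_identical(as.character(code_change(srh_spec, 2, 3)), "improved")
  expect_identical(as.character(code_change(srh_spec, 2, 2)), "unchanged")
  # higher-is-worse flips the mapping
  expect_identical(as.character(code_change(med_spec, 2, 5)), "worsened")
  expect_identical(as.character(code_change(med_spec, 5, 2)), "improved")
  # missing either wave (e.g. death before the second survey) gives NA
  expect_true(is.na(code_change(srh_spec, 3, NA)))
  expect_true(is.na(code_change(srh_spec, NA, 2)))
  # levels are ordered worsened < unchanged < improved
  expect_true(is.ordered(code_change(srh_spec, 1, 1)))
  expect_identical(levels(code_change(srh_spec, 1, 1)),
                   c("worsened", "unchanged", "improved"))
})

test_that("change coding is antisymmetric and shift-invariant", {
  set.seed(31)
  w1 <- sample(0:4, 40, replace = TRUE)
  w2 <- sample(0:4, 40, replace = TRUE)
  fwd <- code_change(srh_spec, w1, w2)
  rev <- code_change(srh_spec, w2, w1)
  expect_identical(fwd == "improved", rev == "worsened")
  expect_identical(fwd == "unchanged", rev == "unchanged")
  expect_identical(code_change(srh_spec, w1 + 7, w2 + 7), fwd)
})

test_that("change coding refuses nominal and undirected variables", {
  nom <- variable_spec("disease", "nominal", waves = "baseline_only")
  expect_error(code_change(nom, 0, 1), "nominal")
  undir <- variable_spec("education", "continuous", "undirected",
                         "baseline_only")
  expect_error(code_change(undir, 1, 2), "direction")
  # and the spec constructor itself rejects incoherent combinations
  expect_error(variable_spec("d", "nominal", "higher_is_better"),
               "direction")
  expect_error(variable_spec("e", "ordinal", "undirected", "both_waves"),
               "direction")
})

test_that("build_feature_table emits the two analysis modes correctly", {
  specs <- rbind(
    variable_spec("srh", "ordinal", "higher_is_better", "both_waves", 0, 4),
    variable_spec("education", "continuous", "undirected", "baseline_only"),
    variable_spec("adl", "continuous", "higher_is_better", "both_waves",
                  0, 15),
    variable_spec("disease", "nominal", waves = "baseline_only")
  )
  base <- data.frame(srh = c(3, 2, 1, NA), education = c(9, 4, 6, 8),
                     adl = c(15, 10, 12, 14),
                     disease = c("yes", "no", "no", "yes"))
  w2 <- data.frame(srh = c(2, 2, NA, 3), adl = c(11, 10, NA, NA))

  m1 <- build_feature_table(base, specs = specs, mode = "baseline_only")
  expect_identical(names(m1), specs$name)
  expect_identical(m1$srh, base$srh)
  expect_true(is.factor(m1$disease))

  m2 <- build_feature_table(base, w2, specs, "baseline_plus_changes")
  expect_identical(names(m2), c(specs$name, "srh_change", "adl_change"))
  expect_equal(nrow(m2), nrow(base))              # rows never dropped
  # auto representation: ordinal -> categorical, continuous -> difference
  expect_identical(as.character(m2$srh_change),
                   c("worsened", "unchanged", NA, NA))
  expect_identical(m2$adl_change, c(-4, 0, NA, NA))

  m2c <- build_feature_table(base, w2, specs, "baseline_plus_changes",
                             change_representation = "categorical")
  expect_identical(as.character(m2c$adl_change),
                   c("worsened", "unchanged", NA, NA))

  # no change-eligible variables: mode 2 degenerates to mode 1
  b_only <- specs[specs$waves == "baseline_only", ]
  expect_identical(
    build_feature_table(base, w2, b_only, "baseline_plus_changes"),
    build_feature_table(base, specs = b_only, mode = "baseline_only"))

  expect_error(build_feature_table(base, NULL, specs,
                                   "baseline_plus_changes"), "wave2")
  expect_error(build_feature_table(base[, 1:2], specs = specs), "lacks")
})

test_that("a specification sheet round-trips through CSV", {
  specs <- default_variable_specs()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(specs, path, row.names = FALSE)
  back <- read_variable_specs(path)
  expect_identical(back$name, specs$name)
  expect_identical(back$kind, specs$kind)
  expect_identical(back$direction, specs$direction)
  expect_identical(back$waves, specs$waves)
  writeLines("name,kind\na,ordinal", path)
  expect_error(read_variable_specs(path), "missing column")
})
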