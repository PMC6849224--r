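test_that("the shipped definitions form the 47-indicator set", {
  defs <- default_indicator_defs()
  expect_length(defs, 47L)
  expect_equal(indicator_kind_counts(defs),
               c(class_sum = 11L, class_ratio = 11L, pair_ratio = 25L))
  nms <- vapply(defs, `[[`, character(1L), "name")
  # the six indicators named in the study must be present
  expect_true(all(c("Total lysoPC", "Total SM", "Total SM / Total PC",
                    "lysoPC a C16:0 / lysoPC a C16:1",
                    "lysoPC a C20:4 / lysoPC a C20:3",
                    "Total AC-DC / Total AC") %in% nms))
  # 16 indicators involve acylcarnitines (denominator for the reported
  # fraction of differentially regulated AC indicators)
  panel <- default_panel()
  involves_ac <- vapply(defs, function(d) {
    sels <- c(d$numerator, d$denominator)
    any(vapply(sels, function(s) {
      any(panel$lipid_class[match(lipidcap:::resolve_members(s, panel),
                                  panel$name)] == "AC")
    }, logical(1L)))
  }, logical(1L))
  expect_identical(sum(involves_ac), 16L)
})

test_that("definition files are validated at load time", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.yaml")
  yaml::write_yaml(list(list(name = "ghost ratio", kind = "pair_ratio",
                             numerator = "PC aa C99:9",
                             denominator = "PC aa C32:0")), bad)
  expect_error(load_indicator_defs(bad), "PC aa C99:9")

  empty <- file.path(dir, "empty.yaml")
  writeLines("[]", empty)
  expect_warning(out <- load_indicator_defs(empty), "empty")
  expect_length(out, 0L)

  nodenom <- file.path(dir, "nodenom.yaml")
  yaml::write_yaml(list(list(name = "r", kind = "class_ratio",
                             numerator = "class:PC")), nodenom)
  expect_error(load_indicator_defs(nodenom), "denominator")
})

test_that("sums and ratios follow their arithmetic definitions", {
  v <- matrix(c(1, 2, 10,
                4, 2, 10), nrow = 2, byrow = TRUE)
  ds <- toy_ds(values = v, n = 2L)   # lysoPC a C16:0, C16:1, PC aa C32:0
  defs <- structure(list(
    list(name = "Total lysoPC", kind = "class_sum",
         numerator = "class:lysoPC"),
    list(name = "lysoPC a C16:0 / lysoPC a C16:1", kind = "pair_ratio",
         numerator = "lysoPC a C16:0", denominator = "lysoPC a C16:1"),
    list(name = "Total lysoPC / Total PC", kind = "class_ratio",
         numerator = "class:lysoPC", denominator = "class:PC")),
    class = "indicator_defs")
  ind <- compute_indicators(ds, defs)
  expect_equal(unname(ind[, "Total lysoPC"]), c(3, 6))
  expect_equal(unname(ind[2, "lysoPC a C16:0 / lysoPC a C16:1"]), 2)
  expect_equal(unname(ind[, "Total lysoPC / Total PC"]), c(0.3, 0.6))
})

test_that("zero denominators are flagged undefined, not propagated", {
  v <- matrix(c(1, 0, 10,
                4, 2, 10), nrow = 2, byrow = TRUE)
  ds <- toy_ds(values = v, n = 2L)
  # analyte 2 is 0 in sample 1 (recorded as measured zero)
  ds$missing_mask[] <- FALSE
  defs <- structure(list(
    list(name = "pair", kind = "pair_ratio",
         numerator = "lysoPC a C16:0", denominator = "lysoPC a C16:1")),
    class = "indicator_defs")
  ind <- compute_indicators(ds, defs)
  expect_true(is.na(ind[1, "pair"]))
  expect_true(attr(ind, "undefined")[1, "pair"])
  expect_equal(unname(ind[2, "pair"]), 2)
})

test_that("indicators require a fully imputed dataset", {
  ds <- toy_ds(values = matrix(c(0.01, rep(5, 17)), 6, 3))
  expect_true(any(ds$missing_mask))
  expect_error(compute_indicators(ds, default_indicator_defs(ds$panel)),
               "impute")
})

test_that("scaling concentrations scales sums and leaves ratios unchanged", {
  cfg <- quick_cfg(seed = 3L)
  ds <- suppressWarnings(impute_missing(generate_cohort(cfg)$dataset))
  defs <- structure(list(
    list(name = "Total PC", kind = "class_sum", numerator = "class:PC"),
    list(name = "Total lysoPC / Total PC", kind = "class_ratio",
         numerator = "class:lysoPC", denominator = "class:PC"),
    list(name = "pair", kind = "pair_ratio",
         numerator = "lysoPC a C16:0", denominator = "lysoPC a C16:1")),
    class = "indicator_defs")
  ind1 <- compute_indicators(ds, defs)
  k <- 3.7
  ds2 <- lipid_dataset(ds$panel, ds$samples, ds$values * k,
                       missing_mask = ds$missing_mask)
  ind2 <- compute_indicators(ds2, defs)
  expect_equal(ind2[, "Total PC"], k * ind1[, "Total PC"])
  expect_equal(ind2[, 2:3], ind1[, 2:3], tolerance = 1e-12)
})

test_that("every default indicator is computable on the default cohort", {
  coh <- generate_cohort(generator_config(seed = 13L))
  ds <- suppressWarnings(impute_missing(coh$dataset))
  ind <- compute_indicators(ds, default_indicator_defs(ds$panel))
  expect_identical(ncol(ind), 47L)
  expect_false(any(attr(ind, "undefined")))
  expect_false(anyNA(ind))
  sums <- ind[, attr(ind, "kind") == "class_sum"]
  expect_true(all(sums >= 0))
})
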