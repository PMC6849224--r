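test_that("the same seed reproduces the cohort bit for bit", {
  a <- generate_cohort(quick_cfg(seed = 42L))
  b <- generate_cohort(quick_cfg(seed = 42L))
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$dataset$missing_mask, b$dataset$missing_mask)
  expect_identical(a$dataset$samples, b$dataset$samples)
  expect_identical(a$truth$analyte, b$truth$analyte)
  c_ <- generate_cohort(quick_cfg(seed = 43L))
  expect_false(identical(a$dataset$values, c_$dataset$values))
})

test_that("the default cohort reproduces the study schedule", {
  coh <- generate_cohort(generator_config(seed = 7L))
  s <- coh$dataset$samples
  expect_identical(length(unique(s$subject_id[s$group == "CAP"])), 29L)
  expect_identical(sum(s$group == "COPD"), 13L)
  expect_identical(sum(s$group == "CTRL"), 33L)
  tp <- table(s$timepoint[s$group == "CAP"])
  expect_equal(unname(tp[c("d1", "d2", "d4")]), c(29, 29, 29),
               ignore_attr = TRUE)
  # one subject lost to follow-up after d4
  expect_equal(unname(tp[c("f1", "f2")]), c(28, 28), ignore_attr = TRUE)
  expect_true(all(s$timepoint[s$group != "CAP"] %in% c("d1", "single")))
})

test_that("concentrations are positive and the mask matches the LODs", {
  coh <- generate_cohort(quick_cfg(seed = 5L))
  ds <- coh$dataset
  expect_true(all(ds$values > 0))
  expected <- sweep(ds$values, 2L, ds$panel$lod, `<`)
  expect_identical(unname(ds$missing_mask), unname(expected))
})

test_that("raising the LOD quantile never unmasks cells", {
  panel <- mini_panel()
  masked_at <- function(q) {
    cfg <- quick_cfg(seed = 9L,
                     lod_quantile = setNames(rep(q, nrow(panel)),
                                             panel$name))
    sum(generate_cohort(cfg)$dataset$missing_mask)
  }
  counts <- vapply(c(0.01, 0.1, 0.3, 0.6), masked_at, numeric(1L))
  expect_true(all(diff(counts) >= 0))
})

test_that("control CRP levels sit near the reference median", {
  coh <- generate_cohort(generator_config(seed = 11L))
  s <- coh$dataset$samples
  med <- median(s$crp[s$group == "CTRL"])
  expect_gt(med, 3.1 / 2)
  expect_lt(med, 3.1 * 2)
})

test_that("zero dispersion collapses marker draws onto the group medians", {
  cfg <- quick_cfg(seed = 1L, inflammation_log_sd = 0)
  cfg$clinical_marker_params <- lapply(cfg$clinical_marker_params,
                                       function(m) {
    m$log_sd[] <- 0
    m
  })
  mk <- generate_clinical_markers(cfg, "CAP", 5L, timepoints = "d1")
  expect_equal(mk$crp, rep(102, 5))
  expect_equal(mk$pct, rep(0.23, 5))
  expect_equal(mk$asm_activity, rep(2.8, 5))
  ctrl <- generate_clinical_markers(cfg, "CTRL", 4L)
  expect_equal(ctrl$crp, rep(3.1, 4))
})

test_that("the generated ASM fold over controls matches the configuration", {
  cfg <- generator_config(seed = 21L)
  folds <- replicate(5, {
    cap <- generate_clinical_markers(cfg, "CAP", 200L, timepoints = "d1")
    ctl <- generate_clinical_markers(cfg, "CTRL", 200L)
    median(cap$asm_activity) / median(ctl$asm_activity)
  })
  expect_true(all(abs(folds - 2.8) <= 0.4))
})

test_that("pooled class fold changes recover the configured multiplier", {
  # the worked case: PC multiplier 0.5 at moderate noise must put the
  # pooled PC median ratio in [0.40, 0.60] in at least 95% of seeds
  profiles <- default_effect_profiles()
  profiles$PC$cap_d1_multiplier <- 0.5
  hits <- 0L
  n_seed <- 50L
  for (s in seq_len(n_seed)) {
    cfg <- generator_config(seed = 300L + s,
                            effect_profiles = profiles,
                            noise_log_sd = 0.2)
    ds <- generate_cohort(cfg)$dataset
    i1 <- sample_index(ds, "CAP", "d1")
    i0 <- sample_index(ds, "CTRL")
    pc <- ds$panel$name[ds$panel$lipid_class == "PC"]
    ratio <- median(ds$values[i1, pc]) / median(ds$values[i0, pc])
    if (ratio >= 0.40 && ratio <= 0.60) hits <- hits + 1L
  }
  expect_gte(hits / n_seed, 0.95)
})

test_that("per-analyte fold changes track the truth sidecar across the multiplier range", {
  for (mult in c(0.2, 0.5, 1.5, 3)) {
    profiles <- default_effect_profiles()
    for (cl in names(profiles)) profiles[[cl]]$cap_d1_multiplier <- mult
    cfg <- quick_cfg(seed = round(1e4 * mult), n_cap = 29L, n_copd = 6L,
                     n_ctrl = 33L, effect_profiles = profiles,
                     analyte_overrides = list(),
                     effect_jitter_rel_sd = 0, subject_log_sd = 0.2,
                     noise_log_sd = 0.2, inflammation_log_sd = 0)
    coh <- generate_cohort(cfg)
    ds <- coh$dataset
    i1 <- sample_index(ds, "CAP", "d1")
    i0 <- sample_index(ds, "CTRL")
    fc <- vapply(seq_len(ncol(ds$values)), function(j) {
      fold_change(ds$values[i1, j], ds$values[i0, j])
    }, numeric(1L))
    truth <- coh$truth$analyte$cap_multiplier
    expect_equal(unname(truth), rep(mult, nrow(ds$panel)))
    rel_err <- abs(fc / truth - 1)
    expect_gte(mean(rel_err <= 0.2), 0.9)
    expect_lte(abs(median(fc) / mult - 1), 0.1)
  }
})

test_that("invalid configurations are rejected up front", {
  expect_error(generator_config(n_cap = 0L), "positive")
  expect_error(generator_config(n_dropout = 29L), "n_dropout")
  profiles <- default_effect_profiles()
  profiles$PC$recovery <- c(1, 0.5, 0.8, 0.3, 0.1)   # not monotone
  expect_error(generator_config(effect_profiles = profiles),
               "non-increasing")
  expect_error(generator_config(effect_profiles = modifyList(
    default_effect_profiles(), list(PC = list(cap_d1_multiplier = -1,
                                              copd_multiplier = 1,
                                              recovery = rep(1, 5))))),
               "positive")
  p <- default_panel()
  expect_error(generator_config(
    lod_quantile = setNames(rep(1.2, nrow(p)), p$name)), "lod_quantile")
})
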