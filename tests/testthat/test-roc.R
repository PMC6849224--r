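test_that("full-data ROC area equals U/(n1*n2) and the brute-force count", {
  set.seed(17)
  for (rep in 1:10) {
    x <- rnorm(14, 1)
    y <- rnorm(11)
    v <- c(x, y)
    lab <- rep(c(TRUE, FALSE), c(14, 11))
    auc <- empirical_auc(v, lab)
    expect_equal(auc, mwu_test(x, y)$statistic / (14 * 11))
    expect_equal(auc, auc_brute(v, lab))
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(2)
  v <- rnorm(40)
  lab <- rep(c(TRUE, FALSE), 20)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, v, quiet = TRUE,
                                        direction = "<")))
  expect_equal(empirical_auc(v, lab), ref, tolerance = 1e-12)
})

test_that("a perfectly separated feature scores AUC 1 under CV", {
  v <- c(rnorm(15, 10), rnorm(15, 0))
  lab <- rep(c(TRUE, FALSE), each = 15)
  cv <- cv_auc(v, lab, seed = 1L)
  expect_equal(cv$mean_auc, 1)
  expect_equal(cv$ci_low, 1)
})

test_that("shuffled labels give chance-level CV AUC", {
  set.seed(99)
  v <- rnorm(60)
  lab <- sample(rep(c(TRUE, FALSE), 30))
  cv <- cv_auc(v, lab, seed = 7L)
  expect_gt(cv$mean_auc, 0.35)
  expect_lt(cv$mean_auc, 0.65)
})

test_that("CV AUC is close to the full-data AUC at moderate sample size", {
  set.seed(41)
  for (rep in 1:3) {
    v <- c(rnorm(30, 1.2), rnorm(30))
    lab <- rep(c(TRUE, FALSE), each = 30)
    cv <- cv_auc(v, lab, seed = rep)
    expect_lt(abs(cv$mean_auc - cv$auc_full), 0.05)
    expect_lte(cv$ci_low, cv$mean_auc)
    expect_gte(cv$ci_high, cv$mean_auc)
  }
})

test_that("negating the feature leaves the CV AUC unchanged, flipping direction", {
  set.seed(4)
  v <- c(rnorm(20, 1), rnorm(20))
  lab <- rep(c(TRUE, FALSE), each = 20)
  up <- cv_auc(v, lab, seed = 12L)
  dn <- cv_auc(-v, lab, seed = 12L)
  expect_equal(up$mean_auc, dn$mean_auc, tolerance = 1e-12)
  expect_identical(up$direction, "up")
  expect_identical(dn$direction, "down")
})

test_that("a class smaller than k is refused with advice", {
  v <- rnorm(8)
  lab <- rep(c(TRUE, FALSE), c(3, 5))
  expect_error(cv_auc(v, lab, k = 5), "k")
})

test_that("the three-criterion rule is applied literally", {
  tab <- data.frame(
    feature = c("a", "b", "c", "d"),
    lipid_class = "PC",
    mean_auc = c(0.85, 0.85, 0.79, 0.90),
    ci_low = c(0.55, 0.45, 0.60, 0.52),
    p_mwu = c(0.01, 0.01, 0.001, 0.2))
  out <- classify_biomarkers(tab)
  got <- setNames(out$is_biomarker, out$feature)
  expect_true(got[["a"]])
  expect_false(got[["b"]])   # CI crosses the chance line
  expect_false(got[["c"]])   # AUC below 0.80
  expect_false(got[["d"]])   # not significant
})

test_that("a strong class-wide PC effect yields PC biomarkers at defaults", {
  coh <- generate_cohort(generator_config(seed = 37L))
  qc <- lod_filter(coh$dataset)
  ds <- suppressWarnings(impute_missing(qc$dataset))
  pc <- ds$panel$name[ds$panel$lipid_class == "PC"][1:20]
  sub <- lipidcap:::ds_subset(ds, j = match(pc, ds$panel$name))
  rt <- roc_table(sub, default_contrasts()$CAP_d1_vs_CTRL, seed = 5L)
  expect_gte(sum(rt$is_biomarker & rt$lipid_class == "PC"), 1L)
})

test_that("oversampling balances the minority arm reproducibly", {
  coh <- generate_cohort(generator_config(seed = 43L))
  ds <- coh$dataset
  ctr <- default_contrasts()$COPD_vs_CTRL      # 13 vs 33
  ov <- oversample_minority(ds, ctr, seed = 6L)
  expect_identical(sum(ov$samples$group == "COPD"), 33L)
  expect_identical(sum(ov$samples$group == "CTRL"), 33L)
  dup <- attr(ov, "duplicates")
  expect_length(dup, 20L)
  expect_true(all(grepl("_dup", dup)))
  # originals all retained
  orig <- ds$samples$sample_id[sample_index(ds, "COPD")]
  expect_true(all(orig %in% ov$samples$sample_id))
  ov2 <- oversample_minority(ds, ctr, seed = 6L)
  expect_identical(ov$samples$sample_id, ov2$samples$sample_id)
  ov3 <- oversample_minority(ds, ctr, seed = 7L)
  expect_false(identical(ov$samples$sample_id, ov3$samples$sample_id))
})

test_that("equal arms pass through oversampling untouched", {
  ds <- toy_ds()                                # 3 CAP vs 3 CTRL
  ctr <- contrast("CAP", "d1", "CTRL", "single")
  ov <- oversample_minority(ds, ctr)
  expect_identical(nrow(ov$values), 6L)
  expect_match(attr(ov, "note"), "balanced")
})

test_that("oversampling preserves the minority median in expectation", {
  coh <- generate_cohort(generator_config(seed = 47L))
  ds <- coh$dataset
  ctr <- default_contrasts()$COPD_vs_CTRL
  j <- match("PC aa C34:4", ds$panel$name)
  orig_med <- median(ds$values[sample_index(ds, "COPD"), j])
  meds <- vapply(1:50, function(s) {
    ov <- oversample_minority(ds, ctr, seed = s)
    median(ov$values[ov$samples$group == "COPD", j])
  }, numeric(1L))
  expect_lt(abs(mean(meds) / orig_med - 1), 0.1)
})

test_that("covariate adjustment leaves an independent covariate harmless", {
  set.seed(61)
  ok <- 0L
  for (rep in 1:10) {
    n <- 80
    lab <- rep(c(TRUE, FALSE), each = n / 2)
    v <- rnorm(n, mean = as.numeric(lab))
    cov <- rbinom(n, 1, 0.3)                 # independent of both
    adj <- covariate_adjusted_test(v, lab, cov)
    raw <- summary(stats::glm(lab ~ scale(v),
                              family = binomial()))$coefficients[2, 4]
    expect_identical(adj$flag, "none")
    if (abs(adj$p - raw) < 0.05) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("a feature identical to the covariate is flagged, not tested", {
  lab <- rep(c(TRUE, FALSE), each = 10)
  cov <- rep(c(1, 0), 10)
  adj <- covariate_adjusted_test(cov, lab, cov)
  expect_identical(adj$flag, "aliased")
  expect_true(is.na(adj$p))
})

test_that("an effect acting only through the covariate loses significance", {
  set.seed(71)
  calm <- 0L
  n_rep <- 40L
  for (rep in seq_len(n_rep)) {
    n <- 70
    cov <- rbinom(n, 1, 0.5)
    lab <- runif(n) < plogis(-1.5 + 3 * cov)     # label driven by covariate
    v <- rnorm(n, mean = 1.2 * cov)              # feature driven by covariate
    adj <- covariate_adjusted_test(v, lab, cov)
    if (is.na(adj$p) || adj$p > 0.05) calm <- calm + 1L
  }
  expect_gte(calm / n_rep, 0.9)
})

test_that("separation is flagged and still yields a finite penalized p", {
  v <- c(rnorm(10, 20), rnorm(10, -20))
  lab <- rep(c(TRUE, FALSE), each = 10)
  cov <- rbinom(20, 1, 0.5)
  adj <- covariate_adjusted_test(v, lab, cov)
  expect_identical(adj$flag, "separation")
  expect_true(is.finite(adj$p))
})
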