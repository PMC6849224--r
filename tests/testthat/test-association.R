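test_that("standardization uses the population variance", {
  z <- standardize_matrix(cbind(a = c(1, 2, 3)))
  # sigma = sqrt(2/3) -> (-1.2247, 0, 1.2247)
  expect_equal(unname(z[, 1]), c(-1.22474487, 0, 1.22474487),
               tolerance = 1e-8)
  # idempotent on already standardized input
  expect_equal(unname(standardize_matrix(z)), unname(z), tolerance = 1e-9)
})

test_that("constant columns are dropped with a warning", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(z <- standardize_matrix(m), "zero-variance")
  expect_identical(colnames(z), "a")
  expect_identical(attr(z, "dropped"), "b")
})

test_that("PCA reconstruction from all components is exact", {
  ds <- suppressWarnings(impute_missing(generate_cohort(
    quick_cfg(seed = 3L))$dataset))
  z <- standardize_matrix(ds$values)
  cm <- pca_centroids(ds, n_components = 2L)
  recon <- cm$scores %*% t(stats::prcomp(z, center = FALSE,
                                         scale. = FALSE)$rotation)
  expect_lt(max(abs(recon - z)), 1e-8)
  expect_true(all(cm$explained_var >= 0 & cm$explained_var <= 1))
  expect_true(all(diff(cm$explained_var) <= 1e-12))
})

test_that("a single-sample cell's centroid is that sample's score", {
  ds <- suppressWarnings(impute_missing(generate_cohort(
    quick_cfg(seed = 31L, n_copd = 6L))$dataset))
  keep <- ds$samples$group != "COPD" |
    ds$samples$sample_id == ds$samples$sample_id[
      match("COPD", ds$samples$group)]
  sub <- lipidcap:::ds_subset(ds, i = which(keep))
  cm <- pca_centroids(sub)
  i <- match("COPD", sub$samples$group)
  row <- cm$centroids[cm$centroids$group == "COPD", ]
  expect_equal(unname(unlist(row[, c("PC1", "PC2")])),
               unname(cm$scores[i, 1:2]))
  expect_identical(row$n, 1L)
})

test_that("centroid distance follows Pythagoras with the sqrt(p) normalization", {
  # two features whose z-space group means differ by exactly (2, 2):
  # f1 = (2,2,0,0) -> z = (1,1,-1,-1); f2 = (0,0,6,6) -> z = (-1,-1,1,1)
  panel <- new_lipid_panel(data.frame(
    name = c("PC aa C32:0", "PC aa C32:1"), lod = c(1e-9, 1e-9)))
  samples <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2"),
    subject_id = c("a1", "a2", "b1", "b2"),
    group = c("CAP", "CAP", "CTRL", "CTRL"),
    timepoint = c("d1", "d1", "single", "single"),
    age = 50, sex = "M", stringsAsFactors = FALSE)
  values <- cbind(c(2, 2, 0, 0), c(0, 0, 6, 6))
  colnames(values) <- panel$name
  ds <- lipid_dataset(panel, samples, values)
  d <- centroid_distance(ds, NULL, "CAP", "CTRL", "d1", NULL)
  expect_equal(d$raw, sqrt(8))
  expect_equal(d$normalized, sqrt(8) / sqrt(2))
  expect_identical(d$n_features, 2L)
  # identical selections -> zero distance
  d0 <- centroid_distance(ds, NULL, "CAP", "CAP", "d1", "d1")
  expect_equal(d0$raw, 0)
})

test_that("distances are invariant to per-feature rescaling before standardization", {
  ds <- suppressWarnings(impute_missing(generate_cohort(
    quick_cfg(seed = 57L))$dataset))
  d1 <- centroid_distance(ds, NULL, "CAP", "CTRL", "d1", NULL)
  scaled <- ds$values %*% diag(seq(0.1, 5, length.out = ncol(ds$values)))
  colnames(scaled) <- colnames(ds$values)
  ds2 <- lipid_dataset(ds$panel, ds$samples, scaled,
                       missing_mask = ds$missing_mask)
  d2 <- centroid_distance(ds2, NULL, "CAP", "CTRL", "d1", NULL)
  expect_equal(d1$raw, d2$raw, tolerance = 1e-10)
})

test_that("CAP centroids drift towards controls along the time course", {
  hits <- 0L
  n_seed <- 10L
  for (s in seq_len(n_seed)) {
    coh <- generate_cohort(generator_config(seed = 600L + s))
    ds <- suppressWarnings(impute_missing(lod_filter(coh$dataset)$dataset))
    dist_t <- vapply(c("d1", "d2", "d4", "f1", "f2"), function(tp) {
      centroid_distance(ds, NULL, "CAP", "CTRL", tp, NULL)$normalized
    }, numeric(1L))
    if (all(diff(dist_t) < 0)) hits <- hits + 1L
  }
  expect_gte(hits / n_seed, 0.9)
})

test_that("Pearson correlation matches its defining formula and affine invariance", {
  ds <- suppressWarnings(impute_missing(generate_cohort(
    quick_cfg(seed = 67L))$dataset))
  # exact relations through the marker column
  ds$samples$crp <- seq_len(nrow(ds$samples)) + 0.5
  f_pos <- cbind(x = 2 * ds$samples$crp)
  f_neg <- cbind(x = -ds$samples$crp + 100)
  expect_equal(pearson_vs_marker(ds, "crp", features = f_pos)$r, 1)
  expect_equal(pearson_vs_marker(ds, "crp", features = f_neg)$r, -1)

  x <- c(1, 2, 4, 5)
  y <- c(1, 3, 3, 5)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(stats::cor(x, y)), r_brute, tolerance = 1e-12)
  sub <- lipidcap:::ds_subset(ds, i = sample_index(ds, "CAP"))
  r0 <- pearson_vs_marker(ds, "crp")$r
  ds2 <- ds
  ds2$samples$crp <- 3 * ds$samples$crp + 7
  expect_equal(pearson_vs_marker(ds2, "crp")$r, r0, tolerance = 1e-12)
})

test_that("zero-variance features are flagged undefined in correlations", {
  ds <- toy_ds()
  ds$samples$crp <- c(5, 9, 2, 8, 1, 7)
  f <- cbind(const = rep(1, 6))
  out <- pearson_vs_marker(ds, "crp", features = f, group = NULL)
  expect_true(out$undefined)
  expect_true(is.na(out$r))
})

test_that("generated CAP lipid-CRP correlations are predominantly negative", {
  coh <- generate_cohort(generator_config(seed = 71L))
  ds <- suppressWarnings(impute_missing(lod_filter(coh$dataset)$dataset))
  out <- pearson_vs_marker(ds, "crp")
  s <- attr(out, "summary")
  expect_gt(s[["n_sig_negative"]], s[["n_sig_positive"]])
  phospho <- out$feature %in% ds$panel$name[
    ds$panel$lipid_class %in% c("PC", "lysoPC", "SM", "SM(OH)")]
  expect_lt(median(out$r[phospho]), 0)
})
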