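# Pipeline orchestration: simulate -> qc -> impute -> indicators -> diff
# -> roc -> lfs -> ordination -> correlate, driven by one configuration,
# with deterministic stage seeds and a machine-readable manifest.

PIPELINE_STAGES <- c("simulate", "qc", "impute", "indicators", "diff",
                     "roc", "lfs", "ordination", "correlate")

#' Build a pipeline run configuration
#'
#' @param generator A `generator_config` for the synthetic cohort (the
#'   pipeline can also be pointed at CSV inputs via `conc_path` /
#'   `meta_path`, in which case the simulate stage only records them).
#' @param conc_path,meta_path Optional measured input CSVs.
#' @param panel Panel used when reading measured inputs.
#' @param min_detect_frac LOD QC threshold (default 0.75).
#' @param fdr FDR level (default 0.05).
#' @param auc_min Biomarker AUC threshold (default 0.80).
#' @param alpha Significance level (default 0.05).
#' @param k,repeats Cross-validation settings (default 5 x 25).
#' @param contrasts Named list of [contrast()]s.
#' @param seed Master seed; per-stage child seeds are derived as
#'   `seed + 97 * stage_index` so stages are independently reproducible.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       conc_path = NULL, meta_path = NULL,
                       panel = default_panel(),
                       min_detect_frac = 0.75, fdr = 0.05,
                       auc_min = 0.80, alpha = 0.05,
                       k = 5L, repeats = 25L,
                       contrasts = default_contrasts(),
                       seed = 1L, out_dir = NULL) {
  chk <- function(x, lo, hi, nm, lo_open = TRUE) {
    bad <- if (lo_open) x <= lo || x > hi else x < lo || x > hi
    if (!is.numeric(x) || length(x) != 1L || bad) {
      stop_lipidcap("%s must lie in (%s, %s]", nm, lo, hi)
    }
  }
  chk(min_detect_frac, 0, 1, "min_detect_frac")
  chk(fdr, 0, 1, "fdr")
  chk(alpha, 0, 1, "alpha")
  chk(auc_min, 0.5, 1, "auc_min")
  if (k < 2L || repeats < 1L) stop_lipidcap("need k >= 2 and repeats >= 1")
  for (ctr in contrasts) stopifnot(inherits(ctr, "contrast"))
  if (is.null(seed)) stop_lipidcap("a seed is required for a pipeline run")
  structure(list(generator = generator, conc_path = conc_path,
                 meta_path = meta_path, panel = panel,
                 min_detect_frac = min_detect_frac, fdr = fdr,
                 auc_min = auc_min, alpha = alpha, k = as.integer(k),
                 repeats = as.integer(repeats), contrasts = contrasts,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# full-panel feature source for the indicator stage: QC-passing analytes
# carry their imputed values, dropped analytes keep the raw reported
# values (below-LOD readouts are still readouts); truly unmeasured cells
# fall back to the conventional LOD/2 substitution
indicator_source <- function(ds_raw, ds_imputed, qc_report) {
  values <- ds_raw$values
  kept <- qc_report$kept
  values[, kept] <- ds_imputed$values
  for (j in which(!kept)) {
    na_cells <- is.na(values[, j])
    values[na_cells, j] <- ds_raw$panel$lod[j] / 2
  }
  lipid_dataset(ds_raw$panel, ds_raw$samples, values,
                missing_mask = matrix(FALSE, nrow(values), ncol(values)))
}

write_stage_csv <- function(df, out_dir, file) {
  path <- file.path(out_dir, file)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order, writes every stage artifact as CSV into
#' `out_dir`, and returns (and writes) a manifest recording stage
#' outputs and their MD5 hashes. Identical configuration and seed give
#' byte-identical outputs and manifest.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return The manifest, invisibly; written to `manifest.json`.
#' @export
run_all <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop_lipidcap("an output directory is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  add_stage <- function(name, paths) {
    hashes <- tools::md5sum(unname(paths))
    names(hashes) <- basename(unname(paths))
    stages[[name]] <<- list(name = name,
                            outputs = as.list(hashes))
  }
  seed_of <- function(stage) stage_seed(config$seed,
                                        match(stage, PIPELINE_STAGES))

  # 1 simulate (or ingest) ----------------------------------------------
  if (is.null(config$conc_path)) {
    gen_cfg <- config$generator
    gen_cfg$seed <- seed_of("simulate")
    cohort <- generate_cohort(gen_cfg)
    ds_raw <- cohort$dataset
    paths <- write_dataset(ds_raw, out_dir)
    paths <- c(paths, write_truth(cohort, out_dir))
  } else {
    ds_raw <- read_dataset(config$conc_path, config$meta_path,
                           config$panel)
    paths <- write_dataset(ds_raw, out_dir)
  }
  add_stage("simulate", paths)

  # 2 qc ------------------------------------------------------------------
  qc <- lod_filter(ds_raw, config$min_detect_frac)
  add_stage("qc", write_stage_csv(as.data.frame(qc$report), out_dir,
                                  "qc_report.csv"))

  # 3 impute ---------------------------------------------------------------
  ds <- impute_missing(qc$dataset)
  add_stage("impute",
            write_dataset(ds, out_dir, prefix = "imputed_")[["concentrations"]])

  # 4 indicators ------------------------------------------------------------
  # indicator definitions may reference analytes that fail the per-analyte
  # detection screen (the instrument reports a value either way), so the
  # indicator source combines imputed values for QC-passing analytes with
  # the raw reported values for the dropped ones
  ds_ind <- indicator_source(ds_raw, ds, qc$report)
  defs <- default_indicator_defs(ds_ind$panel)
  ind <- compute_indicators(ds_ind, defs)
  ind_df <- data.frame(sample_id = ds$samples$sample_id, ind,
                       check.names = FALSE, stringsAsFactors = FALSE)
  add_stage("indicators", write_stage_csv(ind_df, out_dir,
                                          "indicators.csv"))

  # 5 diff -------------------------------------------------------------------
  diffs <- lapply(config$contrasts, function(ctr) {
    differential_table(ds, ctr, indicators = ind, fdr = config$fdr)
  })
  diff_all <- do.call(rbind, lapply(diffs, as.data.frame))
  rownames(diff_all) <- NULL
  add_stage("diff", write_stage_csv(diff_all, out_dir, "differential.csv"))

  # 6 roc --------------------------------------------------------------------
  rocs <- lapply(seq_along(config$contrasts), function(i) {
    roc_table(ds, config$contrasts[[i]], indicators = ind,
              k = config$k, repeats = config$repeats,
              auc_min = config$auc_min, alpha = config$alpha,
              seed = seed_of("roc") + 1000L * i)
  })
  roc_all <- do.call(rbind, lapply(rocs, as.data.frame))
  rownames(roc_all) <- NULL
  add_stage("roc", write_stage_csv(roc_all, out_dir, "roc.csv"))

  # 7 lfs --------------------------------------------------------------------
  has_course <- all(c("d1", "d2", "d4", "f1", "f2") %in%
                      ds$samples$timepoint[ds$samples$group == "CAP"])
  if (has_course) {
    lfs <- lfs_table(ds, indicators = ind)
    add_stage("lfs", write_stage_csv(lfs, out_dir, "lfs.csv"))
  } else {
    add_stage("lfs", write_stage_csv(
      data.frame(note = "no full CAP time course in input"),
      out_dir, "lfs.csv"))
  }

  # 8 ordination ----------------------------------------------------------
  cm <- pca_centroids(ds)
  loadings <- data.frame(feature = rownames(cm$loadings), cm$loadings,
                         check.names = FALSE, stringsAsFactors = FALSE)
  p1 <- write_stage_csv(cm$centroids, out_dir, "centroids.csv")
  p2 <- write_stage_csv(loadings, out_dir, "loadings.csv")
  subsets <- c(list(all = ds$panel$name),
               split(ds$panel$name, ds$panel$lipid_class))
  dist_rows <- list()
  for (nm in names(subsets)) {
    for (g in intersect(c("CAP", "COPD"), ds$samples$group)) {
      tp <- if (g == "CAP") "d1" else NULL
      d <- centroid_distance(ds, subsets[[nm]], g, "CTRL", tp, NULL)
      dist_rows[[paste(nm, g)]] <- data.frame(
        feature_set = nm, group = g, n_features = d$n_features,
        raw = d$raw, normalized = d$normalized,
        stringsAsFactors = FALSE)
    }
  }
  for (g in intersect(c("CAP", "COPD"), ds$samples$group)) {
    tp <- if (g == "CAP") "d1" else NULL
    d <- centroid_distance(ds, ind, g, "CTRL", tp, NULL)
    dist_rows[[paste("indicators", g)]] <- data.frame(
      feature_set = "indicators", group = g, n_features = d$n_features,
      raw = d$raw, normalized = d$normalized, stringsAsFactors = FALSE)
  }
  dist_df <- do.call(rbind, dist_rows)
  rownames(dist_df) <- NULL
  p3 <- write_stage_csv(dist_df, out_dir, "distances.csv")
  add_stage("ordination", c(p1, p2, p3))

  # 9 correlate -----------------------------------------------------------
  cors <- do.call(rbind, lapply(c("crp", "pct"), function(mk) {
    rbind(pearson_vs_marker(ds, mk),
          pearson_vs_marker(ds, mk, features = ind))
  }))
  rownames(cors) <- NULL
  add_stage("correlate", write_stage_csv(cors, out_dir,
                                         "correlations.csv"))

  manifest <- list(
    pipeline = "lipidcap", seed = config$seed,
    thresholds = list(min_detect_frac = config$min_detect_frac,
                      fdr = config$fdr, auc_min = config$auc_min,
                      alpha = config$alpha, k = config$k,
                      repeats = config$repeats),
    contrasts = vapply(config$contrasts, `[[`, character(1L), "name"),
    n_completed = length(stages),
    stages = unname(stages))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Re-reads the stage CSVs and derives the headline tables: per-contrast
#' biomarker counts, the fold-change/AUC/p table, the resolution-marker
#' (LFS vs 1-NDF) ranking, and the correlation summary. Every number is
#' recomputed from the stage artifacts, never cached.
#'
#' @param out_dir Directory of a completed [run_all()].
#' @return A `run_report` list of data frames.
#' @export
report_run <- function(out_dir) {
  man_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop_lipidcap("no manifest.json in '%s'; run_all() first", out_dir)
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  if (manifest$n_completed < length(PIPELINE_STAGES)) {
    stop_lipidcap("run is incomplete (%d/%d stages)",
                  manifest$n_completed, length(PIPELINE_STAGES))
  }
  roc <- utils::read.csv(file.path(out_dir, "roc.csv"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  diff <- utils::read.csv(file.path(out_dir, "differential.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  lfs <- utils::read.csv(file.path(out_dir, "lfs.csv"),
                         check.names = FALSE, stringsAsFactors = FALSE)
  cors <- utils::read.csv(file.path(out_dir, "correlations.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- stats::aggregate(is_biomarker ~ contrast, data = roc, FUN = sum)
  names(counts)[2L] <- "n_biomarkers"
  fc <- diff[, c("feature", "family", "contrast", "fold_change",
                 "p_mwu", "q_bh")]
  auc_cols <- roc[, c("feature", "contrast", "mean_auc", "ci_low",
                      "ci_high", "is_biomarker")]
  fig4 <- merge(fc, auc_cols, by = c("feature", "contrast"),
                sort = FALSE)
  top_resolution <- if ("rank_score" %in% names(lfs)) {
    utils::head(lfs[!lfs$wrong_direction,
                    c("feature", "family", "lfs", "one_minus_ndf",
                      "rank_score")], 15L)
  } else {
    lfs
  }
  cor_summary <- do.call(rbind, lapply(split(cors, cors$marker),
                                       function(d) {
    data.frame(marker = d$marker[1L],
               n_sig_negative = sum(!d$undefined & d$p < 0.05 & d$r < 0),
               n_sig_positive = sum(!d$undefined & d$p < 0.05 & d$r > 0),
               n_features = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(cor_summary) <- NULL
  structure(list(biomarker_counts = counts, marker_table = fig4,
                 top_resolution = top_resolution,
                 correlation_summary = cor_summary,
                 manifest = manifest),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\nBiomarker counts by contrast:\n")
  print(x$biomarker_counts)
  cat("\nTop resolution markers:\n")
  print(utils::head(x$top_resolution, 8L))
  cat("\nCorrelation summary:\n")
  print(x$correlation_summary)
  invisible(x)
}
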