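# The dataset container: a samples x analytes concentration matrix (uM),
# a parallel missingness mask (TRUE = not measured or below the analyte
# LOD), per-sample metadata, and the panel registry. Below-LOD cells keep
# their raw reported value but are flagged in the mask; downstream
# imputation replaces flagged cells.

GROUPS <- c("CAP", "COPD", "CTRL")
TIMEPOINTS <- c("d1", "d2", "d4", "f1", "f2", "single")

#' Assemble a lipid dataset
#'
#' @param panel A `lipid_panel`.
#' @param samples Data frame of per-sample metadata. Required columns:
#'   `sample_id`, `subject_id`, `group` (CAP/COPD/CTRL), `timepoint`
#'   (d1, d2, d4, f1, f2 or single). Optional: `age`, `sex` (F/M),
#'   `crp` (mg/l), `pct` (ng/l), `asm_activity` (arbitrary enzyme units),
#'   `corticosteroid` (logical).
#' @param values Numeric matrix, samples x analytes, concentrations in uM.
#'   Column names must match panel names (panel order is enforced).
#' @param missing_mask Optional logical matrix of the same shape; defaults
#'   to `is.na(values) | values < lod`.
#' @return A `lipid_dataset` list with elements `panel`, `samples`,
#'   `values`, `missing_mask`.
#' @export
lipid_dataset <- function(panel, samples, values, missing_mask = NULL) {
  stopifnot(inherits(panel, "lipid_panel"), is.data.frame(samples))
  values <- as.matrix(values)
  req <- c("sample_id", "subject_id", "group", "timepoint")
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop_lipidcap("sample metadata lacks columns: %s",
                  paste(miss, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_lipidcap("sample_id values are not unique")
  }
  if (!all(samples$group %in% GROUPS)) {
    stop_lipidcap("unknown group: %s",
                  paste(setdiff(samples$group, GROUPS), collapse = ", "))
  }
  if (!all(samples$timepoint %in% TIMEPOINTS)) {
    stop_lipidcap("unknown timepoint: %s",
                  paste(setdiff(samples$timepoint, TIMEPOINTS),
                        collapse = ", "))
  }
  if (nrow(values) != nrow(samples)) {
    stop_lipidcap("values has %d rows but there are %d samples",
                  nrow(values), nrow(samples))
  }
  if (is.null(colnames(values))) {
    if (ncol(values) != nrow(panel)) {
      stop_lipidcap("values has %d columns but the panel has %d analytes",
                    ncol(values), nrow(panel))
    }
    colnames(values) <- panel$name
  }
  unknown <- setdiff(colnames(values), panel$name)
  if (length(unknown)) {
    stop_lipidcap("value columns not in panel: %s",
                  paste(unknown, collapse = ", "))
  }
  panel <- panel[match(colnames(values), panel$name), , drop = FALSE]
  panel <- new_lipid_panel(as.data.frame(panel))
  rownames(values) <- samples$sample_id
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values) |
      sweep(values, 2L, panel$lod, `<`)
    missing_mask[is.na(missing_mask)] <- TRUE
  }
  missing_mask <- as.matrix(missing_mask)
  stopifnot(identical(dim(missing_mask), dim(values)))
  dimnames(missing_mask) <- dimnames(values)
  obs <- values[!missing_mask]
  if (any(is.na(obs)) || any(obs < 0)) {
    stop_lipidcap("non-missing concentrations must be >= 0")
  }
  structure(list(panel = panel, samples = samples, values = values,
                 missing_mask = missing_mask),
            class = "lipid_dataset")
}

#' @export
print.lipid_dataset <- function(x, ...) {
  tab <- table(x$samples$group)
  cat(sprintf(
    "<lipid_dataset> %d samples x %d analytes (%s); %.1f%% cells flagged missing\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    100 * mean(x$missing_mask)))
  invisible(x)
}

#' Number of samples / analytes
#' @param x A `lipid_dataset`.
#' @return Integer vector `c(samples, analytes)`.
#' @export
dim.lipid_dataset <- function(x) dim(x$values)

# subset a dataset by sample index and/or analyte index (internal)
ds_subset <- function(ds, i = NULL, j = NULL) {
  i <- i %||% seq_len(nrow(ds$values))
  j <- j %||% seq_len(ncol(ds$values))
  lipid_dataset(
    panel = new_lipid_panel(as.data.frame(ds$panel[j, , drop = FALSE])),
    samples = ds$samples[i, , drop = FALSE],
    values = ds$values[i, j, drop = FALSE],
    missing_mask = ds$missing_mask[i, j, drop = FALSE]
  )
}

#' Select sample indices by group and timepoint
#'
#' @param ds A `lipid_dataset`.
#' @param group Group label or `NULL` for all.
#' @param timepoint Timepoint label or `NULL` for all.
#' @return Integer vector of row indices.
#' @export
sample_index <- function(ds, group = NULL, timepoint = NULL) {
  keep <- rep(TRUE, nrow(ds$samples))
  if (!is.null(group)) keep <- keep & ds$samples$group %in% group
  if (!is.null(timepoint)) keep <- keep & ds$samples$timepoint %in% timepoint
  which(keep)
}

# -- CSV I/O ----------------------------------------------------------------

#' Read a dataset from concentration and metadata CSV files
#'
#' The concentration file must have `sample_id` as its first column and one
#' column per analyte (uM); the metadata file carries the per-sample
#' covariates. Cells that are empty, `NA`, or below the analyte's LOD are
#' flagged in the missingness mask (below-LOD cells keep their raw value).
#'
#' @param conc_path Path to concentrations CSV.
#' @param meta_path Path to sample metadata CSV.
#' @param panel A `lipid_panel` supplying analyte order and LODs.
#' @return A `lipid_dataset`.
#' @export
read_dataset <- function(conc_path, meta_path, panel = default_panel()) {
  conc <- utils::read.csv(conc_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (df in list(conc, meta)) {
    if (!"sample_id" %in% names(df)) {
      stop_lipidcap("both files must contain a sample_id column")
    }
  }
  analyte_cols <- setdiff(names(conc), "sample_id")
  unknown <- setdiff(analyte_cols, panel$name)
  if (length(unknown)) {
    stop_lipidcap("concentration file has columns not in the panel: %s",
                  paste(unknown, collapse = ", "))
  }
  if (!setequal(conc$sample_id, meta$sample_id)) {
    only_c <- setdiff(conc$sample_id, meta$sample_id)
    only_m <- setdiff(meta$sample_id, conc$sample_id)
    stop_lipidcap(
      "sample_id mismatch between files (only in concentrations: %s; only in metadata: %s)",
      paste(only_c, collapse = ", "), paste(only_m, collapse = ", "))
  }
  meta <- meta[match(conc$sample_id, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if ("corticosteroid" %in% names(meta)) {
    meta$corticosteroid <- as.logical(meta$corticosteroid)
  }
  ord <- panel$name[panel$name %in% analyte_cols]
  values <- as.matrix(conc[, ord, drop = FALSE])
  storage.mode(values) <- "double"
  panel_sub <- new_lipid_panel(
    as.data.frame(panel[match(ord, panel$name), , drop = FALSE]))
  lipid_dataset(panel_sub, meta, values)
}

#' Write a dataset to CSV files
#'
#' Writes `concentrations.csv` (panel column order; unmeasured cells as
#' `NA`, below-LOD cells keep their raw value) and `samples.csv` into
#' `out_dir`. Output is byte-deterministic for a given dataset.
#'
#' @param ds A `lipid_dataset`.
#' @param out_dir Output directory (created if needed).
#' @param prefix Optional file-name prefix.
#' @return Named character vector of the two file paths.
#' @export
write_dataset <- function(ds, out_dir, prefix = "") {
  stopifnot(inherits(ds, "lipid_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  values <- ds$values
  values[is.na(values)] <- NA_real_
  conc <- data.frame(sample_id = ds$samples$sample_id,
                     values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  conc_path <- file.path(out_dir, paste0(prefix, "concentrations.csv"))
  meta_path <- file.path(out_dir, paste0(prefix, "samples.csv"))
  utils::write.csv(conc, conc_path, row.names = FALSE)
  utils::write.csv(ds$samples, meta_path, row.names = FALSE)
  c(concentrations = conc_path, samples = meta_path)
}
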