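# QC filtering by detection fraction and covariate-regression imputation.

#' Filter analytes by limit-of-detection detection fraction
#'
#' Keeps analytes whose measured value exceeded the LOD (i.e. is not
#' flagged missing) in at least `min_detect_frac` of all samples, pooling
#' groups and timepoints. The default threshold keeps an analyte detected
#' in exactly 75% of samples.
#'
#' @param ds A `lipid_dataset`.
#' @param min_detect_frac Minimum detected fraction in (0, 1].
#' @return A list with `dataset` (restricted to kept analytes) and
#'   `report`, a `qc_report` data frame (analyte, class, detected
#'   fraction, kept) with per-class summary counts in
#'   `attr(, "summary")`.
#' @export
lod_filter <- function(ds, min_detect_frac = 0.75) {
  stopifnot(inherits(ds, "lipid_dataset"))
  if (min_detect_frac <= 0 || min_detect_frac > 1) {
    stop_lipidcap("min_detect_frac must lie in (0, 1]")
  }
  if (nrow(ds$values) == 0L || ncol(ds$values) == 0L) {
    stop_lipidcap("cannot QC-filter an empty dataset")
  }
  detected <- colMeans(!ds$missing_mask)
  kept <- detected >= min_detect_frac
  report <- data.frame(
    analyte = ds$panel$name,
    lipid_class = ds$panel$lipid_class,
    detected_fraction = unname(detected),
    kept = unname(kept),
    stringsAsFactors = FALSE)
  summary <- as.data.frame.matrix(
    table(report$lipid_class, factor(report$kept, c(TRUE, FALSE))))
  names(summary) <- c("kept", "dropped")
  attr(report, "summary") <- summary
  attr(report, "min_detect_frac") <- min_detect_frac
  class(report) <- c("qc_report", "data.frame")
  list(dataset = ds_subset(ds, j = which(kept)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d analytes kept (detected fraction >= %.2f)\n",
              sum(x$kept), nrow(x), attr(x, "min_detect_frac")))
  print(attr(x, "summary"))
  invisible(x)
}

#' Impute missing concentrations by covariate regression
#'
#' Fits, per analyte, an ordinary least-squares model of the observed
#' concentrations on age, sex, disease group and sample-collection
#' timepoint, and replaces flagged cells by the model prediction. The
#' model is fitted once on all observed samples jointly; timepoint is
#' coded as categorical indicators, with non-CAP samples mapped to the
#' baseline (d1) reference level so group and timepoint stay separately
#' estimable. Predictions are floored at half the analyte's LOD, since a
#' regression prediction can be negative but a concentration cannot.
#' Observed cells are never altered.
#'
#' @param ds A `lipid_dataset` with metadata columns `age` and `sex`.
#' @return A `lipid_dataset` with no flagged cells.
#' @export
impute_missing <- function(ds) {
  stopifnot(inherits(ds, "lipid_dataset"))
  if (!any(ds$missing_mask)) return(ds)
  for (v in c("age", "sex")) {
    if (!v %in% names(ds$samples)) {
      stop_lipidcap("imputation needs metadata column '%s'", v)
    }
  }
  meta <- ds$samples
  tp_enc <- ifelse(meta$group == "CAP", meta$timepoint, "d1")
  tp_levels <- intersect(TIMEPOINTS, unique(tp_enc))
  mf <- data.frame(
    age = as.numeric(meta$age),
    sex = factor(meta$sex, levels = intersect(c("F", "M"),
                                              unique(meta$sex))),
    group = factor(meta$group, levels = intersect(GROUPS,
                                                  unique(meta$group))),
    timepoint = factor(tp_enc, levels = tp_levels))
  # single-level factors (e.g. a one-group dataset) carry no information
  # and would break the model matrix; drop them from the design
  terms <- c("age",
             names(mf)[vapply(mf, function(v) is.factor(v) &&
                                nlevels(v) >= 2L, logical(1L))])
  X <- stats::model.matrix(stats::reformulate(terms), data = mf)
  p <- ncol(X)
  values <- ds$values
  mask <- ds$missing_mask
  aliased_seen <- FALSE
  for (j in seq_len(ncol(values))) {
    obs <- !mask[, j]
    if (!any(mask[, j])) next
    if (sum(obs) < p + 2L) {
      stop_lipidcap(
        "analyte '%s' has %d observed values; need at least %d to impute",
        ds$panel$name[j], sum(obs), p + 2L)
    }
    fit <- stats::lm.fit(X[obs, , drop = FALSE], values[obs, j])
    beta <- fit$coefficients
    if (anyNA(beta)) {
      aliased_seen <- TRUE
      beta[is.na(beta)] <- 0
    }
    pred <- drop(X %*% beta)
    floor_j <- ds$panel$lod[j] / 2
    values[mask[, j], j] <- pmax(pred[mask[, j]], floor_j)
  }
  if (aliased_seen) {
    warning("rank-deficient imputation design; aliased columns dropped",
            call. = FALSE)
  }
  lipid_dataset(ds$panel, ds$samples, values,
                missing_mask = matrix(FALSE, nrow(values), ncol(values)))
}
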