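# Resolution-marker screening over the CAP time course.
#
# For each feature, the ratios of CAP timepoint medians to the control
# median are fitted to a straight line over ordinal time (d1..f2 mapped
# to 1..5). The linear fitting slope (LFS) measures the speed of
# normalization; the normalized distance to fitting (NDF) -- the sum of
# absolute vertical residuals divided by the ratio range and by the
# number of observations (5) -- measures how linear the trajectory is
# (0 = perfectly linear). Features combining a steep slope towards 1
# with a small NDF track clinical resolution best.

#' Median-ratio time series of a feature
#'
#' @param ds A `lipid_dataset` containing CAP samples at the requested
#'   timepoints and a control group.
#' @param feature Analyte name, or a numeric per-sample vector (e.g. an
#'   indicator column) aligned with `ds$samples`.
#' @param timepoints Ordered CAP timepoints (default d1, d2, d4, f1, f2).
#' @param control_group Reference group (default CTRL, all timepoints).
#' @param feature_name Label used when `feature` is a vector.
#' @return A `median_ratio_series` list: `feature`, `ratios` (one per
#'   timepoint), `x` (ordinal positions), `undefined` (TRUE when the
#'   control median is zero).
#' @export
median_ratio_series <- function(ds, feature,
                                timepoints = c("d1", "d2", "d4", "f1", "f2"),
                                control_group = "CTRL",
                                feature_name = NULL) {
  stopifnot(inherits(ds, "lipid_dataset"))
  if (is.character(feature)) {
    j <- match(feature, colnames(ds$values))
    if (is.na(j)) stop_lipidcap("unknown feature '%s'", feature)
    v <- ds$values[, j]
    feature_name <- feature
  } else {
    v <- as.numeric(feature)
    stopifnot(length(v) == nrow(ds$samples))
    feature_name <- feature_name %||% "feature"
  }
  missing_tp <- character(0L)
  med_case <- vapply(timepoints, function(t) {
    i <- sample_index(ds, "CAP", t)
    x <- v[i]
    x <- x[!is.na(x)]
    if (length(x) < 3L) {
      missing_tp <<- c(missing_tp, t)
      return(NA_real_)
    }
    stats::median(x)
  }, numeric(1L))
  if (length(missing_tp)) {
    stop_lipidcap("CAP timepoints with fewer than 3 samples: %s",
                  paste(missing_tp, collapse = ", "))
  }
  i_ctrl <- sample_index(ds, control_group)
  x_ctrl <- v[i_ctrl]
  x_ctrl <- x_ctrl[!is.na(x_ctrl)]
  if (!length(x_ctrl)) stop_lipidcap("control group is empty")
  med_ctrl <- stats::median(x_ctrl)
  undefined <- !is.finite(med_ctrl) || med_ctrl == 0
  structure(list(feature = feature_name,
                 ratios = if (undefined) rep(NA_real_, length(timepoints))
                          else unname(med_case) / med_ctrl,
                 x = seq_along(timepoints),
                 timepoints = timepoints,
                 undefined = undefined),
            class = "median_ratio_series")
}

#' Linear fitting slope and normalized distance to fitting
#'
#' Ordinary least squares of the median ratios on ordinal time. LFS is
#' the fitted slope (ratio units per timepoint step); NDF is the sum of
#' absolute vertical residuals divided by the range of the ratios
#' (max - min) and by the number of observations. A constant series
#' (zero range) fits its own line perfectly: LFS = 0, NDF = 0.
#'
#' @param series A `median_ratio_series`, or a numeric vector of ratios.
#' @param x Ordinal positions (defaults to 1..n; only used for a vector
#'   input).
#' @return An `lfs_result` list: `feature`, `lfs`, `intercept`, `ndf`,
#'   `ratios`, `undefined`.
#' @export
lfs_ndf <- function(series, x = NULL) {
  if (inherits(series, "median_ratio_series")) {
    ratios <- series$ratios
    x <- series$x
    feature <- series$feature
    undefined <- series$undefined
  } else {
    ratios <- as.numeric(series)
    x <- x %||% seq_along(ratios)
    feature <- "feature"
    undefined <- anyNA(ratios)
  }
  stopifnot(length(ratios) == length(x), length(ratios) >= 2L)
  if (undefined || anyNA(ratios)) {
    return(structure(list(feature = feature, lfs = NA_real_,
                          intercept = NA_real_, ndf = NA_real_,
                          ratios = ratios, undefined = TRUE),
                     class = "lfs_result"))
  }
  rng <- max(ratios) - min(ratios)
  if (rng == 0) {
    return(structure(list(feature = feature, lfs = 0,
                          intercept = ratios[1L], ndf = 0,
                          ratios = ratios, undefined = FALSE),
                     class = "lfs_result"))
  }
  xm <- mean(x)
  ym <- mean(ratios)
  slope <- sum((x - xm) * (ratios - ym)) / sum((x - xm)^2)
  intercept <- ym - slope * xm
  resid <- abs(ratios - (intercept + slope * x))
  ndf <- sum(resid / rng) / length(ratios)
  structure(list(feature = feature, lfs = slope, intercept = intercept,
                 ndf = ndf, ratios = ratios, undefined = FALSE),
            class = "lfs_result")
}

#' @export
print.lfs_result <- function(x, ...) {
  cat(sprintf("<lfs_result> %s: LFS %.4f, NDF %.4f\n", x$feature, x$lfs,
              x$ndf))
  invisible(x)
}

#' Rank features as resolution markers
#'
#' Ranks by `rank_score = |LFS| * (1 - min(NDF, 1))`: a steep, nearly
#' linear trajectory scores highest. Features whose baseline (d1) ratio
#' sits on the wrong side of 1 relative to the slope direction -- i.e.
#' whose trajectory moves *away* from the control level -- are flagged
#' `wrong_direction` so they can be excluded from a resolution read-out.
#' The (LFS, 1 - NDF) scatter coordinates are included so other cuts can
#' be applied.
#'
#' @param results List of `lfs_result` objects.
#' @return Data frame sorted by descending `rank_score`: feature, lfs,
#'   intercept, ndf, one_minus_ndf, d1_ratio, rank_score,
#'   wrong_direction.
#' @export
rank_resolution_markers <- function(results) {
  stopifnot(length(results) >= 1L)
  rows <- lapply(results, function(r) {
    d1 <- r$ratios[1L]
    data.frame(
      feature = r$feature, lfs = r$lfs, intercept = r$intercept,
      ndf = r$ndf,
      one_minus_ndf = 1 - pmin(r$ndf, 1),
      d1_ratio = d1,
      rank_score = abs(r$lfs) * (1 - pmin(r$ndf, 1)),
      wrong_direction = !is.na(r$lfs) & !is.na(d1) &
        ((d1 < 1 & r$lfs < 0) | (d1 > 1 & r$lfs > 0)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$rank_score, out$feature, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Resolution-marker table for analytes and indicators
#'
#' Convenience wrapper: computes the median-ratio series, LFS and NDF for
#' every analyte (and indicator column, when supplied) and returns the
#' ranked table with the per-timepoint ratios attached.
#'
#' @param ds Imputed `lipid_dataset` with the full CAP time course.
#' @param indicators Optional indicator matrix.
#' @param timepoints,control_group Passed to [median_ratio_series()].
#' @return Data frame: ranked markers plus `family` and ratio columns.
#' @export
lfs_table <- function(ds, indicators = NULL,
                      timepoints = c("d1", "d2", "d4", "f1", "f2"),
                      control_group = "CTRL") {
  fm <- feature_matrix(ds, indicators)
  results <- vector("list", ncol(fm$values))
  ratios <- matrix(NA_real_, ncol(fm$values), length(timepoints))
  for (j in seq_len(ncol(fm$values))) {
    sr <- median_ratio_series(ds, fm$values[, j], timepoints,
                              control_group,
                              feature_name = colnames(fm$values)[j])
    results[[j]] <- lfs_ndf(sr)
    ratios[j, ] <- sr$ratios
  }
  tab <- rank_resolution_markers(results)
  colnames(ratios) <- paste0("ratio_", timepoints)
  ord <- match(tab$feature, colnames(fm$values))
  tab$family <- fm$family[ord]
  tab$lipid_class <- fm$lipid_class[ord]
  cbind(tab, as.data.frame(ratios[ord, , drop = FALSE]))
}
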