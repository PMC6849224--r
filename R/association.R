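# Ordination and correlation: PCA centroid trajectories, Euclidean
# "reprogramming distance" between groups in standardized feature space,
# and Pearson correlation of features with CRP/PCT.

#' Standardize a feature matrix
#'
#' Removes the column mean and scales to unit variance, using the
#' population variance (divisor n) for consistency with PCA on
#' standardized data. Zero-variance columns are dropped with a warning.
#'
#' @param values Numeric matrix, samples x features.
#' @return The z-scored matrix; dropped column names in
#'   `attr(, "dropped")`.
#' @export
standardize_matrix <- function(values) {
  values <- as.matrix(values)
  mu <- colMeans(values)
  centered <- sweep(values, 2L, mu)
  sd_pop <- sqrt(colMeans(centered^2))
  drop <- !is.finite(sd_pop) | sd_pop == 0
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance column(s): %s", sum(drop),
                    paste(utils::head(colnames(values)[drop], 5L),
                          collapse = ", ")),
            call. = FALSE)
  }
  z <- sweep(centered[, !drop, drop = FALSE], 2L, sd_pop[!drop], `/`)
  attr(z, "dropped") <- colnames(values)[drop]
  z
}

#' PCA centroids per group and timepoint
#'
#' Principal component analysis of the standardized feature matrix, with
#' the centroid (mean score vector) of every group/timepoint cell, the
#' per-feature loadings, and the explained-variance fractions. Centroids
#' in the full standardized feature space are returned as well.
#'
#' @param ds Imputed `lipid_dataset`.
#' @param features Character vector of analyte names (default: all), or a
#'   numeric matrix of per-sample feature values (e.g. indicators).
#' @param n_components Number of components to report (default 2).
#' @return A `centroid_map` list: `centroids` (data frame with group,
#'   timepoint, n, PC scores), `z_centroids`, `loadings`,
#'   `explained_var`, `scores`.
#' @export
pca_centroids <- function(ds, features = NULL, n_components = 2L) {
  stopifnot(inherits(ds, "lipid_dataset"))
  values <- if (is.matrix(features)) {
    features
  } else if (is.null(features)) {
    ds$values
  } else {
    miss <- setdiff(features, colnames(ds$values))
    if (length(miss)) {
      stop_lipidcap("unknown features: %s", paste(miss, collapse = ", "))
    }
    ds$values[, features, drop = FALSE]
  }
  z <- standardize_matrix(values)
  if (nrow(z) < 2L || ncol(z) < 2L) {
    stop_lipidcap("need at least 2 samples and 2 usable features for PCA")
  }
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  n_components <- min(n_components, ncol(pca$x))
  explained <- pca$sdev^2 / sum(pca$sdev^2)
  cell <- interaction(ds$samples$group, ds$samples$timepoint, drop = TRUE,
                      sep = ":")
  agg <- function(m) {
    out <- rowsum(m, cell) / as.vector(table(cell))
    out
  }
  score_cent <- agg(pca$x[, seq_len(n_components), drop = FALSE])
  z_cent <- agg(z)
  labels <- do.call(rbind, strsplit(rownames(score_cent), ":", fixed = TRUE))
  centroids <- data.frame(group = labels[, 1L], timepoint = labels[, 2L],
                          n = as.integer(table(cell)),
                          score_cent, stringsAsFactors = FALSE,
                          check.names = FALSE)
  rownames(centroids) <- NULL
  structure(list(centroids = centroids, z_centroids = z_cent,
                 loadings = pca$rotation[, seq_len(n_components),
                                         drop = FALSE],
                 explained_var = explained, scores = pca$x),
            class = "centroid_map")
}

#' @export
print.centroid_map <- function(x, ...) {
  cat(sprintf("<centroid_map> %d cells; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$centroids), 100 * x$explained_var[1L],
              100 * (x$explained_var[2L] %||% NA_real_)))
  invisible(x)
}

#' Euclidean distance between group centroids
#'
#' Distance between the mean vectors of two sample selections in the
#' standardized feature space of the full dataset. The normalized
#' distance divides by the square root of the feature count, so panels
#' or subclasses of different sizes are comparable (a per-feature mean
#' displacement); the raw distance is reported alongside.
#'
#' @param ds Imputed `lipid_dataset`.
#' @param features Analyte names, or a numeric feature matrix.
#' @param group_a,group_b Group labels.
#' @param timepoint_a,timepoint_b Timepoint of each selection (`NULL` =
#'   all timepoints of the group).
#' @return List with `raw`, `normalized`, `n_features`.
#' @export
centroid_distance <- function(ds, features = NULL, group_a = "CAP",
                              group_b = "CTRL", timepoint_a = "d1",
                              timepoint_b = NULL) {
  stopifnot(inherits(ds, "lipid_dataset"))
  values <- if (is.matrix(features)) {
    features
  } else if (is.null(features)) {
    ds$values
  } else {
    miss <- setdiff(features, colnames(ds$values))
    if (length(miss)) {
      stop_lipidcap("unknown features: %s", paste(miss, collapse = ", "))
    }
    ds$values[, features, drop = FALSE]
  }
  if (ncol(values) == 0L) stop_lipidcap("empty feature subset")
  i_a <- sample_index(ds, group_a, timepoint_a)
  i_b <- sample_index(ds, group_b, timepoint_b)
  if (!length(i_a) || !length(i_b)) {
    stop_lipidcap("empty sample selection for centroid distance")
  }
  z <- suppressWarnings(standardize_matrix(values))
  d <- colMeans(z[i_a, , drop = FALSE]) - colMeans(z[i_b, , drop = FALSE])
  raw <- sqrt(sum(d^2))
  list(raw = raw, normalized = raw / sqrt(ncol(z)),
       n_features = ncol(z))
}

#' Pearson correlation of features with an inflammation marker
#'
#' Correlates every feature with CRP or PCT over the CAP samples pooled
#' across the time course (d1 through f2).
#'
#' @param ds A `lipid_dataset` whose metadata carries the marker column.
#' @param marker `"crp"` or `"pct"` (any numeric metadata column works).
#' @param features Analyte names (default: all), or a feature matrix.
#' @param group Sample scope (default CAP, all timepoints).
#' @return Data frame: feature, marker, r, p, n, undefined; counts of
#'   significant negative/positive correlations in `attr(, "summary")`.
#' @export
pearson_vs_marker <- function(ds, marker = "crp", features = NULL,
                              group = "CAP") {
  stopifnot(inherits(ds, "lipid_dataset"))
  if (!marker %in% names(ds$samples)) {
    stop_lipidcap("metadata has no column '%s'", marker)
  }
  idx <- sample_index(ds, group)
  m <- as.numeric(ds$samples[[marker]])[idx]
  if (sum(!is.na(m)) < 3L) {
    stop_lipidcap("marker '%s' present for fewer than 3 samples", marker)
  }
  values <- if (is.matrix(features)) {
    features[idx, , drop = FALSE]
  } else if (is.null(features)) {
    ds$values[idx, , drop = FALSE]
  } else {
    ds$values[idx, features, drop = FALSE]
  }
  rows <- lapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    ok <- !is.na(v) & !is.na(m)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0 || stats::sd(m[ok]) == 0) {
      return(data.frame(feature = colnames(values)[j], marker = marker,
                        r = NA_real_, p = NA_real_, n = sum(ok),
                        undefined = TRUE, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(v[ok], m[ok], method = "pearson")
    data.frame(feature = colnames(values)[j], marker = marker,
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !out$undefined
  attr(out, "summary") <- c(
    n_sig_negative = sum(ok & out$p < 0.05 & out$r < 0),
    n_sig_positive = sum(ok & out$p < 0.05 & out$r > 0),
    n_features = nrow(out))
  out
}
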