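# Differential abundance: fold change as the ratio of group medians,
# Mann-Whitney / Kruskal-Wallis tests, Benjamini-Hochberg correction,
# and the ranked differential table.

#' Fold change as ratio of medians
#'
#' @param case_values,control_values Numeric vectors.
#' @return `median(case) / median(control)`, or `NA` (undefined) when the
#'   control median is zero.
#' @export
fold_change <- function(case_values, control_values) {
  stopifnot(length(case_values) > 0L, length(control_values) > 0L)
  m_ctrl <- stats::median(control_values, na.rm = TRUE)
  if (!is.finite(m_ctrl) || m_ctrl == 0) return(NA_real_)
  stats::median(case_values, na.rm = TRUE) / m_ctrl
}

#' Mann-Whitney U test (asymptotic, tie-corrected)
#'
#' Returns the U statistic counting pairs where `x` exceeds `y` (ties
#' count one half), so that `U / (n1 * n2)` is the empirical ROC area of
#' `x` against `y`, together with the two-sided asymptotic p value
#' (normal approximation with tie and continuity corrections).
#'
#' @param x,y Numeric vectors.
#' @return List with `statistic` (U), `p.value`, `degenerate` (TRUE when
#'   every value is tied across both samples, in which case p = 1).
#' @export
mwu_test <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = U, p.value = 1, degenerate = TRUE))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = U, p.value = ht$p.value, degenerate = FALSE)
}

#' Kruskal-Wallis H test (tie-corrected)
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `statistic` (H), `p.value` (chi-square asymptotic),
#'   `degenerate` (all observations tied; H = 0, p = 1).
#' @export
kw_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p.value = 1, degenerate = TRUE))
  }
  ht <- stats::kruskal.test(values, g)
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p values in \[0, 1\].
#' @param fdr False discovery rate for the rejection flags.
#' @return List with `q` (adjusted q values) and `reject`
#'   (`q <= fdr`).
#' @export
bh_adjust <- function(pvals, fdr = 0.05) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1)) {
    stop_lipidcap("p values must lie in [0, 1]")
  }
  if (fdr <= 0 || fdr > 1) stop_lipidcap("fdr must lie in (0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, reject = q <= fdr)
}

significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("p001", "p01", "p05", "ns"), right = FALSE) |>
    as.character()
}

#' Define a two-group contrast
#'
#' @param case_group,control_group Group labels.
#' @param case_timepoint,control_timepoint Timepoint label or `NULL` for
#'   all timepoints of the group.
#' @param name Contrast name; derived from the selections if omitted.
#' @return A `contrast` list.
#' @export
contrast <- function(case_group, case_timepoint = NULL,
                     control_group = "CTRL", control_timepoint = NULL,
                     name = NULL) {
  if (identical(case_group, control_group) &&
      identical(case_timepoint, control_timepoint)) {
    stop_lipidcap("case and control selections are identical")
  }
  lab <- function(g, t) if (is.null(t)) g else paste(g, t, sep = "_")
  structure(list(case = list(group = case_group,
                             timepoint = case_timepoint),
                 control = list(group = control_group,
                                timepoint = control_timepoint),
                 name = name %||% paste(lab(case_group, case_timepoint),
                                        "vs",
                                        lab(control_group,
                                            control_timepoint),
                                        sep = "_")),
            class = "contrast")
}

#' Baseline contrasts of the study design
#'
#' @return Named list: CAP d1 vs controls, COPD vs controls, CAP d1 vs
#'   COPD.
#' @export
default_contrasts <- function() {
  list(
    CAP_d1_vs_CTRL = contrast("CAP", "d1", "CTRL", NULL),
    COPD_vs_CTRL = contrast("COPD", NULL, "CTRL", NULL),
    CAP_d1_vs_COPD = contrast("CAP", "d1", "COPD", NULL)
  )
}

contrast_index <- function(ds, ctr) {
  i_case <- sample_index(ds, ctr$case$group, ctr$case$timepoint)
  i_ctrl <- sample_index(ds, ctr$control$group, ctr$control$timepoint)
  if (length(i_case) < 3L || length(i_ctrl) < 3L) {
    stop_lipidcap("contrast '%s' selects fewer than 3 samples per arm",
                  ctr$name)
  }
  list(case = i_case, control = i_ctrl)
}

# feature matrix + family labels for analytes and (optionally) indicators
feature_matrix <- function(ds, indicators = NULL) {
  values <- ds$values
  family <- rep("analyte", ncol(values))
  lipid_class <- ds$panel$lipid_class
  if (!is.null(indicators)) {
    values <- cbind(values, indicators)
    family <- c(family, rep("indicator", ncol(indicators)))
    lipid_class <- c(lipid_class, rep("indicator", ncol(indicators)))
  }
  list(values = values, family = family, lipid_class = lipid_class)
}

#' Ranked differential abundance table for one contrast
#'
#' For every feature (analytes, plus indicators when supplied): fold
#' change (ratio of case to control medians), two-sided Mann-Whitney p,
#' and BH q computed within each feature family separately (analytes and
#' indicators are corrected as independent families). Optionally adds a
#' Kruskal-Wallis p across the CAP timepoints. The table is sorted by
#' descending fold change.
#'
#' @param ds Imputed `lipid_dataset`.
#' @param ctr A [contrast()].
#' @param indicators Optional indicator matrix from
#'   [compute_indicators()].
#' @param fdr FDR level for the rejection flags.
#' @param kw_timepoints If `TRUE`, add `p_kw` across CAP timepoints.
#' @return Data frame of class `diff_table`: feature, family, class,
#'   fold_change, p_mwu, q_bh, significance/FDR tiers, rejection flag.
#' @export
differential_table <- function(ds, ctr, indicators = NULL, fdr = 0.05,
                               kw_timepoints = FALSE) {
  stopifnot(inherits(ds, "lipid_dataset"), inherits(ctr, "contrast"))
  if (any(ds$missing_mask)) {
    stop_lipidcap("impute before differential testing")
  }
  idx <- contrast_index(ds, ctr)
  fm <- feature_matrix(ds, indicators)
  n_feat <- ncol(fm$values)
  fc <- p <- rep(NA_real_, n_feat)
  for (j in seq_len(n_feat)) {
    xc <- fm$values[idx$case, j]
    xk <- fm$values[idx$control, j]
    ok_c <- !is.na(xc)
    ok_k <- !is.na(xk)
    if (sum(ok_c) < 3L || sum(ok_k) < 3L) next  # undefined indicator cells
    fc[j] <- fold_change(xc[ok_c], xk[ok_k])
    p[j] <- mwu_test(xc[ok_c], xk[ok_k])$p.value
  }
  q <- rep(NA_real_, n_feat)
  for (fam in unique(fm$family)) {
    sel <- fm$family == fam & !is.na(p)
    if (any(sel)) q[sel] <- bh_adjust(p[sel], fdr)$q
  }
  out <- data.frame(
    feature = colnames(fm$values),
    family = fm$family,
    lipid_class = fm$lipid_class,
    contrast = ctr$name,
    fold_change = fc,
    p_mwu = p,
    q_bh = q,
    tier_p = significance_tier(p),
    tier_fdr = significance_tier(q),
    reject_fdr = !is.na(q) & q <= fdr,
    stringsAsFactors = FALSE)
  if (kw_timepoints) {
    tps <- intersect(TIMEPOINTS, unique(ds$samples$timepoint[
      ds$samples$group == "CAP"]))
    out$p_kw <- NA_real_
    if (length(tps) >= 2L) {
      for (j in seq_len(n_feat)) {
        gl <- lapply(tps, function(t) {
          v <- fm$values[sample_index(ds, "CAP", t), j]
          v[!is.na(v)]
        })
        if (all(vapply(gl, length, integer(1L)) >= 3L)) {
          out$p_kw[j] <- kw_test(gl)$p.value
        }
      }
    }
  }
  out <- out[order(-out$fold_change, out$feature, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("diff_table", "data.frame")
  out
}
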