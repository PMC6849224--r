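# Repeated stratified cross-validated ROC analysis, the three-criterion
# biomarker rule, minority oversampling, and the covariate-adjusted
# logistic check.

#' Empirical ROC area
#'
#' Rank-based area under the ROC curve of `values` for `labels`
#' (TRUE = case). Equals U / (n1 * n2) from the Mann-Whitney statistic.
#'
#' @param values Numeric scores.
#' @param labels Logical vector, TRUE = case.
#' @return AUC in \[0, 1\].
#' @export
empirical_auc <- function(values, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n2 <- sum(!labels)
  stopifnot(n1 > 0L, n2 > 0L)
  r <- rank(values)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# stratified fold ids: each class split as evenly as possible over k folds
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# univariate logistic scorer fitted on the training fold only (feature
# standardized with training mean/sd -- no information leakage)
logistic_fold_auc <- function(values, labels, train, test) {
  mu <- mean(values[train])
  sd_tr <- stats::sd(values[train])
  if (!is.finite(sd_tr) || sd_tr == 0) sd_tr <- 1
  z_tr <- (values[train] - mu) / sd_tr
  z_te <- (values[test] - mu) / sd_tr
  fit <- suppressWarnings(stats::glm.fit(
    cbind(1, z_tr), as.numeric(labels[train]),
    family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  score <- stats::plogis(beta[1L] + beta[2L] * z_te)
  empirical_auc(score, labels[test])
}

#' Cross-validated AUC with percentile confidence interval
#'
#' Stratified k-fold cross-validation repeated `repeats` times; in each
#' fold a univariate logistic regression is trained on the standardized
#' feature (training-fold standardization) and the out-of-fold ROC area
#' recorded. The point estimate is the mean over all `k * repeats` fold
#' AUCs and the CI the 2.5/97.5 percentile of their distribution.
#'
#' @param values Numeric feature vector.
#' @param labels Logical vector, TRUE = case.
#' @param k Number of folds (default 5).
#' @param repeats Number of CV repetitions (default 25).
#' @param seed Optional seed for the fold assignments.
#' @return A `cv_auc` list: `mean_auc`, `ci_low`, `ci_high`,
#'   `fold_aucs`, `auc_full` (full-data rank AUC), `direction`
#'   (`"up"` when cases run higher), `n_case`, `n_control`.
#' @export
cv_auc <- function(values, labels, k = 5L, repeats = 25L, seed = NULL) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(labels))
  n1 <- sum(labels)
  n2 <- sum(!labels)
  if (min(n1, n2) < k) {
    stop_lipidcap(
      "smallest class has %d samples; use k <= %d folds", min(n1, n2),
      min(n1, n2))
  }
  fold_aucs <- with_seed(seed, {
    out <- numeric(k * repeats)
    pos <- 0L
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(labels, k)
      for (f in seq_len(k)) {
        pos <- pos + 1L
        test <- which(fold == f)
        train <- which(fold != f)
        out[pos] <- logistic_fold_auc(values, labels, train, test)
      }
    }
    out
  })
  auc_full <- empirical_auc(values, labels)
  ci <- unname(stats::quantile(fold_aucs, c(0.025, 0.975)))
  structure(list(mean_auc = mean(fold_aucs), ci_low = ci[1L],
                 ci_high = ci[2L], fold_aucs = fold_aucs,
                 auc_full = auc_full,
                 direction = if (auc_full >= 0.5) "up" else "down",
                 n_case = n1, n_control = n2),
            class = "cv_auc")
}

#' @export
print.cv_auc <- function(x, ...) {
  cat(sprintf(
    "<cv_auc> mean AUC %.3f [%.3f, %.3f] over %d folds (%d vs %d, %s)\n",
    x$mean_auc, x$ci_low, x$ci_high, length(x$fold_aucs), x$n_case,
    x$n_control, x$direction))
  invisible(x)
}

#' Per-feature ROC table for one contrast
#'
#' Runs [cv_auc()] and the Mann-Whitney test for every feature (analytes
#' plus indicators when supplied) on the case/control samples of the
#' contrast, then applies the three-criterion biomarker rule via
#' [classify_biomarkers()].
#'
#' @param ds Imputed `lipid_dataset`.
#' @param ctr A [contrast()].
#' @param indicators Optional indicator matrix.
#' @param k,repeats Cross-validation settings.
#' @param auc_min,alpha Biomarker thresholds.
#' @param seed Seed for the fold assignments (per-feature seeds are
#'   derived deterministically).
#' @return Data frame of class `roc_table`.
#' @export
roc_table <- function(ds, ctr, indicators = NULL, k = 5L, repeats = 25L,
                      auc_min = 0.80, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(ds, "lipid_dataset"), inherits(ctr, "contrast"))
  if (any(ds$missing_mask)) stop_lipidcap("impute before ROC analysis")
  idx <- contrast_index(ds, ctr)
  fm <- feature_matrix(ds, indicators)
  n_feat <- ncol(fm$values)
  rows <- vector("list", n_feat)
  for (j in seq_len(n_feat)) {
    v <- c(fm$values[idx$case, j], fm$values[idx$control, j])
    lab <- rep(c(TRUE, FALSE), c(length(idx$case), length(idx$control)))
    ok <- !is.na(v)
    v <- v[ok]
    lab <- lab[ok]
    if (min(sum(lab), sum(!lab)) < k) next
    cv <- cv_auc(v, lab, k = k, repeats = repeats,
                 seed = if (is.null(seed)) NULL else seed + j)
    p <- mwu_test(v[lab], v[!lab])$p.value
    rows[[j]] <- data.frame(
      feature = colnames(fm$values)[j], family = fm$family[j],
      lipid_class = fm$lipid_class[j], contrast = ctr$name,
      mean_auc = cv$mean_auc, ci_low = cv$ci_low, ci_high = cv$ci_high,
      auc_full = cv$auc_full, p_mwu = p, direction = cv$direction,
      n_case = cv$n_case, n_control = cv$n_control,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  classify_biomarkers(out, auc_min = auc_min, alpha = alpha)
}

#' Apply the three-criterion biomarker rule
#'
#' A feature is called a biomarker candidate when its mean
#' cross-validated AUC is at least `auc_min` ("excellent
#' classification"), its asymptotic Mann-Whitney p is below `alpha`, and
#' the lower 95% CI bound does not cross the chance line at 0.50.
#'
#' @param rocs Data frame with columns `mean_auc`, `ci_low`, `p_mwu`.
#' @param auc_min AUC threshold (default 0.80).
#' @param alpha Significance threshold (default 0.05).
#' @return `rocs` with an `is_biomarker` column, sorted by descending
#'   mean AUC; per-class biomarker counts in `attr(, "summary")`.
#' @export
classify_biomarkers <- function(rocs, auc_min = 0.80, alpha = 0.05) {
  need <- c("mean_auc", "ci_low", "p_mwu")
  miss <- setdiff(need, names(rocs))
  if (length(miss)) {
    stop_lipidcap("roc table lacks columns: %s", paste(miss, collapse = ", "))
  }
  rocs$is_biomarker <- rocs$mean_auc >= auc_min &
    rocs$p_mwu < alpha & rocs$ci_low > 0.5
  rocs <- rocs[order(-rocs$mean_auc, rocs$feature), , drop = FALSE]
  rownames(rocs) <- NULL
  if ("lipid_class" %in% names(rocs)) {
    tab <- table(rocs$lipid_class[rocs$is_biomarker])
    attr(rocs, "summary") <- data.frame(
      lipid_class = names(tab), n_biomarkers = as.integer(tab),
      stringsAsFactors = FALSE)
  }
  class(rocs) <- c("roc_table", "data.frame")
  rocs
}

#' Oversample the minority arm of a contrast
#'
#' Resamples the smaller of the two contrast arms with replacement until
#' it matches the larger arm (modelling what biomarker yield would look
#' like at equal group sizes), and returns a dataset restricted to the
#' two arms. Duplicated samples get a `_dupN` suffix and are listed in
#' `attr(, "duplicates")`. With equal arms the selection is returned
#' unchanged, with a note.
#'
#' @param ds A `lipid_dataset`.
#' @param ctr A [contrast()].
#' @param seed Seed for the resampling.
#' @return A `lipid_dataset` containing the two (balanced) arms.
#' @export
oversample_minority <- function(ds, ctr, seed = NULL) {
  stopifnot(inherits(ds, "lipid_dataset"), inherits(ctr, "contrast"))
  idx <- contrast_index(ds, ctr)
  n_case <- length(idx$case)
  n_ctrl <- length(idx$control)
  if (n_case == n_ctrl) {
    out <- ds_subset(ds, i = c(idx$case, idx$control))
    attr(out, "note") <- "arms already balanced; no oversampling applied"
    attr(out, "duplicates") <- character(0L)
    return(out)
  }
  minority <- if (n_case < n_ctrl) idx$case else idx$control
  majority <- if (n_case < n_ctrl) idx$control else idx$case
  extra <- with_seed(seed,
    sample(minority, length(majority) - length(minority), replace = TRUE))
  sel <- c(idx$case, idx$control, extra)
  out <- ds_subset_dup(ds, sel)
  attr(out, "duplicates") <-
    out$samples$sample_id[seq.int(n_case + n_ctrl + 1L, length(sel))]
  out
}

# subset allowing repeated rows; repeated sample_ids get _dupN suffixes
ds_subset_dup <- function(ds, i) {
  samples <- ds$samples[i, , drop = FALSE]
  ids <- samples$sample_id
  counts <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  ids[counts > 1L] <- sprintf("%s_dup%d", ids[counts > 1L],
                              counts[counts > 1L] - 1L)
  samples$sample_id <- ids
  rownames(samples) <- NULL
  lipid_dataset(ds$panel, samples, ds$values[i, , drop = FALSE],
                missing_mask = ds$missing_mask[i, , drop = FALSE])
}

#' Logistic regression p value adjusted for a binary covariate
#'
#' Fits `label ~ feature + covariate` (feature standardized) and returns
#' the Wald p for the feature term, to check whether a group difference
#' survives adjustment for, e.g., corticosteroid treatment. Complete or
#' quasi-complete separation is detected; in that case a ridge-penalized
#' fit (small fixed L2 penalty on the standardized coefficients) is used
#' and noted in the output.
#'
#' @param values Numeric feature.
#' @param labels Logical outcome, TRUE = case.
#' @param covariate Binary covariate (logical or 0/1).
#' @return List with `p` (Wald p for the feature), `coef` (feature log
#'   odds per SD), and `flag` (`"none"`, `"separation"` or
#'   `"aliased"`).
#' @export
covariate_adjusted_test <- function(values, labels, covariate) {
  labels <- as.logical(labels)
  covariate <- as.numeric(covariate)
  stopifnot(length(values) == length(labels),
            length(covariate) == length(labels))
  z <- as.numeric(scale(values))
  if (!all(is.finite(z))) {
    return(list(p = NA_real_, coef = NA_real_, flag = "aliased"))
  }
  if (stats::var(covariate) > 0 &&
      isTRUE(all.equal(abs(stats::cor(z, covariate)), 1))) {
    return(list(p = NA_real_, coef = NA_real_, flag = "aliased"))
  }
  df <- data.frame(y = as.numeric(labels), z = z, cov = covariate)
  fit <- suppressWarnings(
    stats::glm(y ~ z + cov, data = df, family = stats::binomial()))
  sep <- !fit$converged ||
    any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) ||
    any(abs(stats::coef(fit)[-1L]) > 15, na.rm = TRUE)
  if (!sep) {
    sm <- summary(fit)$coefficients
    return(list(p = sm["z", "Pr(>|z|)"], coef = sm["z", "Estimate"],
                flag = "none"))
  }
  rg <- ridge_logistic(cbind(1, z, covariate), as.numeric(labels),
                       lambda = 0.1)
  list(p = rg$p[2L], coef = rg$beta[2L], flag = "separation")
}

# Newton-Raphson logistic regression with a small L2 penalty on the
# non-intercept coefficients; Wald p from the penalized information
ridge_logistic <- function(X, y, lambda = 0.1, maxit = 50L) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(H)))
  zstat <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pnorm(-abs(zstat)))
}
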