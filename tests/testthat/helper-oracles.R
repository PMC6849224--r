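# Independent brute-force oracles and small fixtures, kept deliberately
# naive so they stay independent of the implementation they check.

# Benjamini-Hochberg step-up by direct definition: q_(i) is the minimum
# over j >= i of p_(j) * m / j, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  ps <- p[ord]
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# ROC area by exhaustive pair counting
auc_brute <- function(values, labels) {
  cases <- values[labels]
  ctrls <- values[!labels]
  wins <- 0
  for (a in cases) for (b in ctrls) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(cases) * length(ctrls))
}

# exact two-sided permutation p value for the Mann-Whitney U statistic
perm_mwu_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- abs(u_of(seq_len(n1)) - n1 * (n - n1) / 2)
  splits <- utils::combn(n, n1)
  hits <- 0
  for (k in seq_len(ncol(splits))) {
    u <- sum(rank(pooled)[splits[, k]]) - n1 * (n1 + 1) / 2
    if (abs(u - n1 * (n - n1) / 2) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(splits)
}

# OLS slope/intercept from the normal equations, written out longhand
ols_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Kruskal-Wallis H by the textbook rank formula with tie correction
kw_brute <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  offsets <- cumsum(c(0, head(lengths(groups), -1)))
  h <- 0
  for (g in seq_along(groups)) {
    idx <- offsets[g] + seq_len(length(groups[[g]]))
    h <- h + length(idx) * (mean(r[idx]) - (n + 1) / 2)^2
  }
  h <- 12 / (n * (n + 1)) * h
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# -- fixtures ---------------------------------------------------------------

# small panel subset (valid lipid_panel, not the 145-analyte default);
# avoids the poor-detection analytes, which need the QC filter before
# imputation is possible
mini_panel <- function() {
  p <- default_panel()
  poor <- names(which(lipidcap:::default_lod_quantiles(p) >= 0.5))
  ok <- !p$name %in% poor
  keep <- c(which(ok & p$lipid_class == "PC")[1:8],
            which(ok & p$lipid_class == "lysoPC")[1:4],
            which(ok & p$lipid_class == "SM")[1:3],
            which(ok & p$lipid_class == "SM(OH)")[1],
            which(p$name %in% c("C0", "C2", "C3", "C5")))
  new_lipid_panel(as.data.frame(p[keep, ]))
}

quick_cfg <- function(...) {
  args <- list(n_cap = 8L, n_copd = 6L, n_ctrl = 8L, n_dropout = 1L,
               panel = mini_panel())
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(generator_config, args)
}

# tiny handcrafted dataset: 3 analytes, explicit LODs
toy_ds <- function(values = NULL, n = 6L) {
  panel <- new_lipid_panel(data.frame(
    name = c("lysoPC a C16:0", "lysoPC a C16:1", "PC aa C32:0"),
    lod = c(0.05, 0.05, 0.05), stringsAsFactors = FALSE))
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    subject_id = sprintf("P%02d", seq_len(n)),
    group = rep(c("CAP", "CTRL"), length.out = n),
    timepoint = rep(c("d1", "single"), length.out = n),
    age = seq(40, by = 5, length.out = n),
    sex = rep(c("F", "M", "M", "F"), length.out = n),
    stringsAsFactors = FALSE)
  if (is.null(values)) {
    values <- matrix(seq_len(n * 3), n, 3)
  }
  colnames(values) <- panel$name
  lipid_dataset(panel, samples, values)
}
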