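# Seeded synthetic cohort generator.
#
# Concentrations are log-normal: for sample s (subject with latent
# inflammation scalar L_s), analyte a of class c at timepoint t,
#
#   log C_{s,a} = mu_a + u_{s,a} + L_s * r_c(t) * log m_a + eps_{s,a,t}
#
# where mu_a is the analyte's baseline log-median, u_{s,a} a per-subject
# biological effect constant over the time course, m_a the per-analyte
# disease multiplier (class multiplier with relative jitter), r_c(t) the
# class recovery fraction (1 at d1, decaying towards 0 at follow-up), and
# eps measurement noise. Controls have no disease term. The same latent
# L_s scales the CRP/PCT/ASM medians, which yields the negative
# lipid-inflammation correlations seen in acute pneumonia without
# hard-coding correlation targets.

#' Class-level disease effect profiles
#'
#' Default multiplicative effects of disease on analyte concentrations by
#' lipid class: strongest decrease in PC, then lysoPC, then SM in CAP;
#' acylcarnitines flat; ceramides up. COPD effects are milder. The
#' `recovery` vector maps CAP timepoints d1, d2, d4, f1, f2 to the
#' fraction of the log-effect remaining (1 at admission, non-increasing).
#'
#' @return Named list (one entry per lipid class) of lists with elements
#'   `cap_d1_multiplier`, `copd_multiplier`, `recovery`.
#' @export
default_effect_profiles <- function() {
  list(
    PC = list(cap_d1_multiplier = 0.42, copd_multiplier = 0.75,
              recovery = c(1, 0.92, 0.80, 0.68, 0.55)),
    lysoPC = list(cap_d1_multiplier = 0.55, copd_multiplier = 0.80,
                  recovery = c(1, 0.75, 0.50, 0.25, 0.05)),
    SM = list(cap_d1_multiplier = 0.70, copd_multiplier = 0.95,
              recovery = c(1, 0.85, 0.65, 0.45, 0.25)),
    `SM(OH)` = list(cap_d1_multiplier = 0.70, copd_multiplier = 0.95,
                    recovery = c(1, 0.85, 0.65, 0.45, 0.25)),
    AC = list(cap_d1_multiplier = 1.0, copd_multiplier = 1.0,
              recovery = c(1, 1, 1, 1, 1)),
    CER = list(cap_d1_multiplier = 1.6, copd_multiplier = 1.3,
               recovery = c(1, 0.80, 0.55, 0.30, 0.10))
  )
}

# per-analyte departures from the class profile: the two analytes that go
# *up* in CAP (the short-chain acylcarnitine C5 and PC ae C36:0), selected
# sphingomyelins up in COPD, and ceramide-specific effects
default_analyte_overrides <- function() {
  list(
    "C5"          = list(cap = 1.5, copd = 1.2),
    "PC ae C36:0" = list(cap = 1.3, copd = 1.1),
    "SM C16:0"    = list(cap = 0.90, copd = 1.35),
    "SM C18:0"    = list(cap = 0.90, copd = 1.35),
    "SM C18:1"    = list(cap = 0.90, copd = 1.35),
    "Cer C16:0"   = list(cap = 1.8, copd = 1.3),
    "Cer C18:0"   = list(cap = 1.6, copd = 1.2),
    "Cer C24:0"   = list(cap = 1.0, copd = 1.0),
    "Cer C24:1"   = list(cap = 1.3, copd = 1.1)
  )
}

# LOD placement, as a quantile of each analyte's control marginal
# distribution. Phospholipids sit far above the assay LOD (quantile 1e-6);
# ten well-detected acylcarnitines sit closer (0.03); the analytes known
# to detect poorly get 0.5 and are expected to fail the 75% rule, so the
# default cohort reproduces the ~111-of-145 QC outcome with acylcarnitines
# the worst-detected class.
default_lod_quantiles <- function(panel) {
  q <- rep(1e-6, nrow(panel))
  names(q) <- panel$name
  ac <- panel$name[panel$lipid_class == "AC"]
  ac_kept <- c("C0", "C2", "C3", "C4", "C5", "C8", "C10", "C12",
               "C16", "C18")
  q[intersect(ac, ac_kept)] <- 0.03
  q[setdiff(ac, ac_kept)] <- 0.5
  poor <- intersect(c("PC aa C26:0", "lysoPC a C26:1",
                      "SM C26:0", "SM C26:1"), panel$name)
  q[poor] <- 0.5
  q
}

#' Clinical marker generator parameters
#'
#' Group medians follow the study-population table (CRP mg/l: 102 / 14 /
#' 3.1; PCT ng/l: 0.23 / 0.09 / 0.02) and the reported acid
#' sphingomyelinase activity folds over controls (2.8 in CAP, 1.75 in
#' COPD; control median fixed at 1 arbitrary unit). `recovery` decays the
#' CAP log-fold towards the control median by the second follow-up;
#' `floor` is the assay's lower reporting limit.
#'
#' @return Named list of per-marker parameter lists.
#' @export
default_marker_params <- function() {
  list(
    crp = list(median = c(CAP = 102, COPD = 14, CTRL = 3.1),
               log_sd = c(CAP = 0.6, COPD = 0.5, CTRL = 0.25),
               floor = 3.1,
               recovery = c(1, 0.75, 0.50, 0.20, 0.05)),
    pct = list(median = c(CAP = 0.23, COPD = 0.09, CTRL = 0.02),
               log_sd = c(CAP = 0.8, COPD = 0.6, CTRL = 0.3),
               floor = 0.02,
               recovery = c(1, 0.70, 0.45, 0.15, 0.05)),
    asm = list(median = c(CAP = 2.8, COPD = 1.75, CTRL = 1.0),
               log_sd = c(CAP = 0.36, COPD = 0.36, CTRL = 0.36),
               floor = NA_real_,
               recovery = c(1, 0.80, 0.55, 0.30, 0.10))
  )
}

#' Build a generator configuration
#'
#' Defaults encode the emulated study: 29 CAP subjects sampled at five
#' timepoints (one lost to follow-up after d4), 13 COPD exacerbations and
#' 33 controls sampled once, class-specific CAP downregulation with
#' recovery, milder and qualitatively different COPD effects, flat
#' acylcarnitines, LOD censoring, and clinical-marker distributions.
#'
#' @param n_cap,n_copd,n_ctrl Subject counts per group.
#' @param timepoints CAP sampling timepoints, in order.
#' @param n_dropout CAP subjects lost to follow-up after d4.
#' @param panel A `lipid_panel`.
#' @param baseline_log_mean,baseline_log_sd Per-class location and
#'   between-analyte spread of baseline log-concentrations (log uM).
#' @param effect_profiles See [default_effect_profiles()].
#' @param analyte_overrides Named list of per-analyte `cap`/`copd`
#'   multiplier overrides.
#' @param effect_jitter_rel_sd Relative jitter of per-analyte log
#'   multipliers around the class value (classes with multiplier 1 stay
#'   exactly null).
#' @param subject_log_sd Between-subject biological log-SD, constant over
#'   the time course.
#' @param noise_log_sd Measurement noise log-SD per observation.
#' @param inflammation_log_sd Log-SD of the per-subject latent
#'   inflammation scalar shared by lipid effects and clinical markers.
#' @param lod_quantile Named per-analyte quantiles of the control marginal
#'   at which LODs are placed; see [default_lod_quantiles()].
#' @param clinical_marker_params See [default_marker_params()].
#' @param age_median,age_sd,age_range Age distribution (years).
#' @param sex_f_prob,corticosteroid_prob Named per-group probabilities.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cap = 29L, n_copd = 13L, n_ctrl = 33L,
                             timepoints = c("d1", "d2", "d4", "f1", "f2"),
                             n_dropout = 1L,
                             panel = default_panel(),
                             baseline_log_mean = c(PC = log(10),
                                                   lysoPC = log(8),
                                                   SM = log(15),
                                                   `SM(OH)` = log(3),
                                                   AC = log(0.15),
                                                   CER = log(0.5)),
                             baseline_log_sd = c(PC = 1.0, lysoPC = 0.8,
                                                 SM = 0.9, `SM(OH)` = 0.7,
                                                 AC = 1.0, CER = 0.6),
                             effect_profiles = default_effect_profiles(),
                             analyte_overrides = default_analyte_overrides(),
                             effect_jitter_rel_sd = 0.25,
                             subject_log_sd = 0.30,
                             noise_log_sd = 0.15,
                             inflammation_log_sd = 0.3,
                             lod_quantile = default_lod_quantiles(panel),
                             clinical_marker_params = default_marker_params(),
                             age_median = 60, age_sd = 15,
                             age_range = c(24, 90),
                             sex_f_prob = c(CAP = 0.38, COPD = 0.46,
                                            CTRL = 0.36),
                             corticosteroid_prob = c(CAP = 0.22,
                                                     COPD = 0.62,
                                                     CTRL = 0.033),
                             seed = 1L) {
  cfg <- structure(
    list(n_cap = as.integer(n_cap), n_copd = as.integer(n_copd),
         n_ctrl = as.integer(n_ctrl), timepoints = timepoints,
         n_dropout = as.integer(n_dropout), panel = panel,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         effect_profiles = effect_profiles,
         analyte_overrides = analyte_overrides,
         effect_jitter_rel_sd = effect_jitter_rel_sd,
         subject_log_sd = subject_log_sd,
         noise_log_sd = noise_log_sd,
         inflammation_log_sd = inflammation_log_sd,
         lod_quantile = lod_quantile,
         clinical_marker_params = clinical_marker_params,
         age_median = age_median, age_sd = age_sd, age_range = age_range,
         sex_f_prob = sex_f_prob,
         corticosteroid_prob = corticosteroid_prob,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (any(c(cfg$n_cap, cfg$n_copd, cfg$n_ctrl) <= 0L)) {
    stop_lipidcap("group sizes must be positive")
  }
  if (cfg$n_dropout < 0L || cfg$n_dropout >= cfg$n_cap) {
    stop_lipidcap("n_dropout must be in [0, n_cap)")
  }
  if (!inherits(cfg$panel, "lipid_panel")) {
    stop_lipidcap("panel must be a lipid_panel")
  }
  classes <- unique(cfg$panel$lipid_class)
  for (v in c("baseline_log_mean", "baseline_log_sd")) {
    miss <- setdiff(classes, names(cfg[[v]]))
    if (length(miss)) {
      stop_lipidcap("%s lacks classes: %s", v, paste(miss, collapse = ", "))
    }
  }
  for (cl in classes) {
    pr <- cfg$effect_profiles[[cl]]
    if (is.null(pr)) stop_lipidcap("no effect profile for class %s", cl)
    if (pr$cap_d1_multiplier <= 0 || pr$copd_multiplier <= 0) {
      stop_lipidcap("multipliers must be positive (class %s)", cl)
    }
    rec <- pr$recovery
    if (length(rec) != length(cfg$timepoints) || rec[1L] != 1 ||
        any(diff(rec) > 0) || any(rec < 0 | rec > 1)) {
      stop_lipidcap(
        "recovery for class %s must start at 1, be non-increasing, within [0,1]",
        cl)
    }
  }
  for (ov in cfg$analyte_overrides) {
    if (any(unlist(ov) <= 0)) stop_lipidcap("override multipliers must be > 0")
  }
  q <- cfg$lod_quantile
  miss <- setdiff(cfg$panel$name, names(q))
  if (length(miss)) {
    stop_lipidcap("lod_quantile lacks analytes: %s",
                  paste(utils::head(miss, 5L), collapse = ", "))
  }
  if (any(q < 0 | q >= 1)) stop_lipidcap("lod_quantile must lie in [0, 1)")
  disp <- c(cfg$effect_jitter_rel_sd, cfg$subject_log_sd,
            cfg$noise_log_sd, cfg$inflammation_log_sd)
  if (any(disp < 0)) stop_lipidcap("dispersions must be non-negative")
  for (m in cfg$clinical_marker_params) {
    miss <- setdiff(GROUPS, names(m$median))
    if (length(miss)) {
      stop_lipidcap("marker parameters lack groups: %s",
                    paste(miss, collapse = ", "))
    }
    if (any(m$median <= 0) || any(m$log_sd < 0)) {
      stop_lipidcap("marker medians must be > 0 and log_sd >= 0")
    }
  }
  invisible(cfg)
}

# per-analyte log multipliers with relative jitter; overrides replace the
# class multiplier but keep the analyte's jitter draw
analyte_log_multipliers <- function(cfg) {
  panel <- cfg$panel
  A <- nrow(panel)
  eps_cap <- stats::rnorm(A, 0, cfg$effect_jitter_rel_sd)
  eps_copd <- stats::rnorm(A, 0, cfg$effect_jitter_rel_sd)
  base_cap <- log(vapply(cfg$effect_profiles[panel$lipid_class],
                         `[[`, numeric(1L), "cap_d1_multiplier"))
  base_copd <- log(vapply(cfg$effect_profiles[panel$lipid_class],
                          `[[`, numeric(1L), "copd_multiplier"))
  for (nm in names(cfg$analyte_overrides)) {
    j <- match(nm, panel$name)
    if (is.na(j)) next
    base_cap[j] <- log(cfg$analyte_overrides[[nm]]$cap)
    base_copd[j] <- log(cfg$analyte_overrides[[nm]]$copd)
  }
  list(cap = base_cap * (1 + eps_cap),
       copd = base_copd * (1 + eps_copd))
}

marker_log_value <- function(params, group, t_idx, L) {
  med <- params$median
  lf <- log(med[[group]]) - log(med[["CTRL"]])
  rec <- if (group == "CAP") params$recovery[t_idx] else 1
  log(med[["CTRL"]]) + L * rec * lf
}

draw_marker <- function(params, group, t_idx, L) {
  mu <- marker_log_value(params, group, t_idx, L)
  v <- exp(mu + stats::rnorm(length(L), 0, params$log_sd[[group]]))
  if (is.finite(params$floor)) v <- pmax(v, params$floor)
  v
}

#' Generate clinical inflammation markers for one group
#'
#' Draws per-subject CRP, PCT and acid sphingomyelinase activity from the
#' configured log-normal group distributions; CAP trajectories decay
#' towards the control median by the second follow-up visit. Markers are
#' coupled to the latent inflammation scalar that also drives lipid
#' effects, so correlation screening has signal.
#'
#' @param config A `generator_config`.
#' @param group `"CAP"`, `"COPD"` or `"CTRL"`.
#' @param n Number of subjects.
#' @param timepoints Timepoints to draw (default: config timepoints for
#'   CAP, a single baseline draw otherwise).
#' @param inflammation Optional vector of latent scalars (length `n`);
#'   drawn from the configured log-normal if `NULL`.
#' @return Data frame with `subject`, `timepoint`, `crp`, `pct`,
#'   `asm_activity`.
#' @export
generate_clinical_markers <- function(config, group, n,
                                      timepoints = NULL,
                                      inflammation = NULL) {
  stopifnot(group %in% GROUPS)
  if (is.null(timepoints)) {
    timepoints <- if (group == "CAP") config$timepoints else "d1"
  }
  if (is.null(inflammation)) {
    inflammation <- exp(stats::rnorm(n, 0, config$inflammation_log_sd))
  }
  stopifnot(length(inflammation) == n)
  out <- vector("list", length(timepoints))
  for (k in seq_along(timepoints)) {
    out[[k]] <- data.frame(
      subject = seq_len(n), timepoint = timepoints[k],
      crp = draw_marker(config$clinical_marker_params$crp, group, k,
                        inflammation),
      pct = draw_marker(config$clinical_marker_params$pct, group, k,
                        inflammation),
      asm_activity = draw_marker(config$clinical_marker_params$asm, group,
                                 k, inflammation),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic cohort
#'
#' Simulates the full study structure under the configured effect model
#' and returns the dataset together with a truth sidecar (the multipliers
#' and marker medians actually used), enabling parameter-recovery tests.
#' LODs are placed at the configured quantile of each analyte's control
#' marginal distribution; values drawn below the LOD keep their raw value
#' but are flagged missing. The same seed reproduces the cohort exactly.
#'
#' @param config A `generator_config`.
#' @return A list of class `lipid_cohort`: `dataset` (a `lipid_dataset`)
#'   and `truth` (per-analyte multipliers and effect matrix, per-sample
#'   marker medians, LODs).
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  panel <- cfg$panel
  A <- nrow(panel)
  cls <- panel$lipid_class
  tps <- cfg$timepoints
  n_tp <- length(tps)

  base_mu <- cfg$baseline_log_mean[cls] +
    stats::rnorm(A, 0, cfg$baseline_log_sd[cls])
  logm <- analyte_log_multipliers(cfg)
  recovery <- t(vapply(cfg$effect_profiles[cls], `[[`, numeric(n_tp),
                       "recovery"))          # A x n_tp

  # subjects -----------------------------------------------------------
  groups <- c(rep("CAP", cfg$n_cap), rep("COPD", cfg$n_copd),
              rep("CTRL", cfg$n_ctrl))
  ids <- c(sprintf("CAP%02d", seq_len(cfg$n_cap)),
           sprintf("COPD%02d", seq_len(cfg$n_copd)),
           sprintf("CTRL%02d", seq_len(cfg$n_ctrl)))
  n_subj <- length(ids)
  age <- round(pmin(cfg$age_range[2L], pmax(cfg$age_range[1L],
               stats::rnorm(n_subj, cfg$age_median, cfg$age_sd))))
  sex <- ifelse(stats::runif(n_subj) < cfg$sex_f_prob[groups], "F", "M")
  cortico <- stats::runif(n_subj) < cfg$corticosteroid_prob[groups]
  L <- ifelse(groups == "CTRL", 1,
              exp(stats::rnorm(n_subj, 0, cfg$inflammation_log_sd)))
  u <- matrix(stats::rnorm(n_subj * A, 0, cfg$subject_log_sd),
              n_subj, A)                       # subject x analyte

  dropped <- if (cfg$n_dropout > 0L) {
    sample(seq_len(cfg$n_cap), cfg$n_dropout)
  } else integer(0L)

  # sample schedule -----------------------------------------------------
  rows <- list()
  for (s in seq_len(n_subj)) {
    tp_s <- if (groups[s] == "CAP") {
      if (s %in% dropped) intersect(tps, c("d1", "d2", "d4")) else tps
    } else if (groups[s] == "COPD") "d1" else "single"
    rows[[s]] <- data.frame(subject = s, timepoint = tp_s,
                            stringsAsFactors = FALSE)
  }
  sched <- do.call(rbind, rows)
  n_samp <- nrow(sched)
  t_idx <- match(sched$timepoint, tps)
  t_idx[is.na(t_idx)] <- 1L                    # COPD d1 / CTRL single

  # concentrations ------------------------------------------------------
  logc <- matrix(0, n_samp, A)
  for (i in seq_len(n_samp)) {
    s <- sched$subject[i]
    g <- groups[s]
    shift <- if (g == "CAP") {
      L[s] * recovery[, t_idx[i]] * logm$cap
    } else if (g == "COPD") {
      L[s] * logm$copd
    } else {
      numeric(A)
    }
    logc[i, ] <- base_mu + u[s, ] + shift +
      stats::rnorm(A, 0, cfg$noise_log_sd)
  }
  values <- exp(logc)
  colnames(values) <- panel$name

  # LOD and mask ---------------------------------------------------------
  sd_ctrl <- sqrt(cfg$subject_log_sd^2 + cfg$noise_log_sd^2)
  q <- cfg$lod_quantile[panel$name]
  lod <- exp(base_mu + stats::qnorm(q) * sd_ctrl)
  panel$lod <- pmax(unname(lod), .Machine$double.xmin)
  panel <- new_lipid_panel(as.data.frame(panel))

  # clinical markers ------------------------------------------------------
  mk <- cfg$clinical_marker_params
  crp <- pct <- asm <- numeric(n_samp)
  crp_med <- pct_med <- asm_med <- numeric(n_samp)
  for (i in seq_len(n_samp)) {
    s <- sched$subject[i]
    g <- groups[s]
    k <- t_idx[i]
    crp[i] <- draw_marker(mk$crp, g, k, L[s])
    pct[i] <- draw_marker(mk$pct, g, k, L[s])
    asm[i] <- draw_marker(mk$asm, g, k, L[s])
    crp_med[i] <- exp(marker_log_value(mk$crp, g, k, L[s]))
    pct_med[i] <- exp(marker_log_value(mk$pct, g, k, L[s]))
    asm_med[i] <- exp(marker_log_value(mk$asm, g, k, L[s]))
  }

  samples <- data.frame(
    sample_id = paste(ids[sched$subject], sched$timepoint, sep = "_"),
    subject_id = ids[sched$subject],
    group = groups[sched$subject],
    timepoint = sched$timepoint,
    age = age[sched$subject],
    sex = sex[sched$subject],
    crp = crp, pct = pct, asm_activity = asm,
    corticosteroid = cortico[sched$subject],
    stringsAsFactors = FALSE)

  ds <- lipid_dataset(panel, samples, values)

  cap_effect <- exp(recovery * logm$cap)       # A x n_tp, at L = 1
  colnames(cap_effect) <- tps
  truth <- list(
    analyte = data.frame(
      name = panel$name, lipid_class = cls,
      cap_multiplier = exp(logm$cap),
      copd_multiplier = exp(logm$copd),
      baseline_median = exp(base_mu),
      lod = panel$lod,
      stringsAsFactors = FALSE),
    cap_effect = cap_effect,
    markers = data.frame(
      sample_id = samples$sample_id,
      crp_median = crp_med, pct_median = pct_med, asm_median = asm_med,
      inflammation = L[sched$subject],
      stringsAsFactors = FALSE),
    config = cfg)
  structure(list(dataset = ds, truth = truth), class = "lipid_cohort")
}

#' @export
print.lipid_cohort <- function(x, ...) {
  cat("<lipid_cohort>\n")
  print(x$dataset)
  invisible(x)
}

#' Write a cohort's truth sidecar to CSV
#'
#' @param cohort A `lipid_cohort`.
#' @param out_dir Output directory.
#' @return Named character vector of file paths.
#' @export
write_truth <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  an <- cbind(cohort$truth$analyte,
              as.data.frame(cohort$truth$cap_effect,
                            check.names = FALSE))
  p1 <- file.path(out_dir, "truth_analytes.csv")
  p2 <- file.path(out_dir, "truth_markers.csv")
  utils::write.csv(an, p1, row.names = FALSE)
  utils::write.csv(cohort$truth$markers, p2, row.names = FALSE)
  c(truth_analytes = p1, truth_markers = p2)
}
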