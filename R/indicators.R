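# Metabolic indicators: class sums, class ratios and lipid-pair ratios
# computed per sample from a configurable definition file. The shipped
# default file defines 47 indicators (11 class sums, 11 class ratios,
# 25 pair ratios), including the indicators quoted in the field: total
# lysoPC, total SM, total SM / total PC, lysoPC a C16:0 / C16:1,
# lysoPC a C20:4 / C20:3, and dicarboxyl-AC / total AC.

INDICATOR_KINDS <- c("class_sum", "class_ratio", "pair_ratio")

#' Load indicator definitions
#'
#' Reads a YAML file of indicator definitions. Each entry has `name`,
#' `kind` (`class_sum`, `class_ratio` or `pair_ratio`), a `numerator` and
#' (for ratios) a `denominator`. Numerators and denominators are either a
#' list of analyte names or a class selector string
#' `"class:<classes>[;bond:<aa|ae|a>][;moiety:<OH|DC>][;db_min:<n>][;db_max:<n>]"`,
#' e.g. `"class:PC;bond:aa"` or `"class:SM,SM(OH)"`.
#'
#' @param path Path to a YAML definition file.
#' @param panel Panel against which analyte references are validated.
#' @return A list of indicator definitions, class `indicator_defs`.
#' @export
load_indicator_defs <- function(path, panel = default_panel()) {
  entries <- yaml::read_yaml(path)
  if (length(entries) == 0L) {
    warning("indicator definition file is empty", call. = FALSE)
    return(structure(list(), class = "indicator_defs"))
  }
  defs <- lapply(entries, function(e) {
    if (is.null(e$name) || is.null(e$kind)) {
      stop_lipidcap("indicator entries need 'name' and 'kind'")
    }
    if (!e$kind %in% INDICATOR_KINDS) {
      stop_lipidcap("indicator '%s': unknown kind '%s'", e$name, e$kind)
    }
    if (e$kind == "class_sum" && !is.null(e$denominator)) {
      stop_lipidcap("indicator '%s': class_sum takes no denominator", e$name)
    }
    if (e$kind != "class_sum" && is.null(e$denominator)) {
      stop_lipidcap("indicator '%s': ratios need a denominator", e$name)
    }
    list(name = e$name, kind = e$kind,
         numerator = e$numerator, denominator = e$denominator)
  })
  nms <- vapply(defs, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop_lipidcap("duplicate indicator names: %s",
                  paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  # resolve every reference now so bad files fail at load time
  for (d in defs) {
    resolve_members(d$numerator, panel, d$name)
    if (!is.null(d$denominator)) resolve_members(d$denominator, panel, d$name)
  }
  structure(defs, class = "indicator_defs")
}

#' The default 47-indicator definition set
#'
#' @param panel Panel used for reference validation.
#' @return An `indicator_defs` list.
#' @export
default_indicator_defs <- function(panel = default_panel()) {
  path <- system.file("extdata", "indicators.yaml", package = "lipidcap",
                      mustWork = TRUE)
  load_indicator_defs(path, panel)
}

# resolve a selector (analyte name vector or "class:..." string) to
# panel analyte names
resolve_members <- function(sel, panel, indicator = "?") {
  sel <- unlist(sel, use.names = FALSE)
  if (length(sel) == 1L && grepl("^class:", sel)) {
    parts <- strsplit(sel, ";", fixed = TRUE)[[1L]]
    keep <- rep(TRUE, nrow(panel))
    for (p in parts) {
      kv <- strsplit(p, ":", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) {
        stop_lipidcap("indicator '%s': bad selector token '%s'", indicator, p)
      }
      val <- kv[2L]
      keep <- keep & switch(kv[1L],
        class = panel$lipid_class %in% strsplit(val, ",", fixed = TRUE)[[1L]],
        bond = panel$bond_type == val,
        moiety = panel$moiety == val,
        db_min = panel$n_double_bonds >= as.integer(val),
        db_max = panel$n_double_bonds <= as.integer(val),
        stop_lipidcap("indicator '%s': unknown selector key '%s'",
                      indicator, kv[1L]))
    }
    members <- panel$name[keep]
    if (!length(members)) {
      stop_lipidcap("indicator '%s': selector '%s' matches no analyte",
                    indicator, sel)
    }
    return(members)
  }
  missing <- setdiff(sel, panel$name)
  if (length(missing)) {
    stop_lipidcap("indicator '%s': unknown analyte reference: %s",
                  indicator, paste(missing, collapse = ", "))
  }
  sel
}

#' Indicator counts by kind
#'
#' @param defs An `indicator_defs` list.
#' @return Named integer vector over `class_sum`, `class_ratio`,
#'   `pair_ratio`.
#' @export
indicator_kind_counts <- function(defs) {
  kinds <- vapply(defs, `[[`, character(1L), "kind")
  tab <- table(factor(kinds, levels = INDICATOR_KINDS))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Compute the metabolic indicator matrix
#'
#' Class sums are per-sample sums of member concentrations (uM); ratios
#' divide the per-sample numerator aggregate by the denominator aggregate
#' and are dimensionless. A sample with a zero denominator gets `NA` for
#' that indicator and is flagged in the `undefined` attribute.
#'
#' @param ds A fully imputed `lipid_dataset` (no flagged cells).
#' @param defs Indicator definitions; default: the shipped 47.
#' @return Numeric matrix samples x indicators with attributes `kind`
#'   (per-indicator) and `undefined` (logical matrix).
#' @export
compute_indicators <- function(ds, defs = default_indicator_defs(ds$panel)) {
  stopifnot(inherits(ds, "lipid_dataset"))
  if (any(ds$missing_mask)) {
    stop_lipidcap(
      "dataset still has flagged missing cells; run impute_missing() first")
  }
  values <- ds$values
  n <- nrow(values)
  out <- matrix(NA_real_, n, length(defs))
  colnames(out) <- vapply(defs, `[[`, character(1L), "name")
  rownames(out) <- rownames(values)
  undef <- matrix(FALSE, n, length(defs), dimnames = dimnames(out))
  agg <- function(sel, d) {
    members <- resolve_members(sel, ds$panel, d)
    rowSums(values[, members, drop = FALSE])
  }
  for (k in seq_along(defs)) {
    d <- defs[[k]]
    num <- agg(d$numerator, d$name)
    if (d$kind == "class_sum") {
      out[, k] <- num
    } else {
      den <- agg(d$denominator, d$name)
      bad <- den == 0
      undef[bad, k] <- TRUE
      out[, k] <- ifelse(bad, NA_real_, num / den)
    }
  }
  attr(out, "kind") <- vapply(defs, `[[`, character(1L), "kind")
  attr(out, "undefined") <- undef
  out
}
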