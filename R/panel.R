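# Analyte nomenclature and the assay panel registry.
#
# Naming follows the targeted flow-injection lipidomics convention:
# "Cx:y" gives the total side-chain carbons (x) and double bonds (y);
# phosphatidylcholines carry a bond-type token ("aa" = two ester-linked
# fatty acids, "ae" = one ether-linked fatty alcohol), lysoPC carry "a";
# hydroxysphingomyelins are written "SM (OH) Cx:y"; acylcarnitines are
# bare "Cn", "Cn:m", optionally with a hydroxyl ("-OH") or dicarboxyl
# ("-DC", "-M-DC") moiety suffix; ceramides are written "Cer Cx:y".

LIPID_CLASSES <- c("PC", "lysoPC", "SM", "SM(OH)", "AC", "CER")

#' Parse a panel analyte name
#'
#' Decomposes an analyte label into lipid class, bond type, chain length and
#' number of double bonds.
#'
#' @param name Analyte label, e.g. `"PC aa C34:4"`, `"lysoPC a C16:0"`,
#'   `"SM (OH) C22:1"`, `"C5-DC"`, `"Cer C16:0"`.
#' @return A list with elements `name`, `lipid_class`, `bond_type`
#'   (`"aa"`, `"ae"`, `"a"` or `"none"`), `n_carbons`, `n_double_bonds`
#'   and `moiety` (`"OH"`, `"DC"` or `"none"`; acylcarnitines only).
#' @examples
#' parse_analyte_name("PC aa C34:4")
#' parse_analyte_name("SM (OH) C22:1")
#' @export
parse_analyte_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name))) {
    stop_lipidcap("analyte name must be a single non-empty string")
  }
  nm <- trimws(name)

  grab <- function(pattern) {
    m <- regmatches(nm, regexec(pattern, nm))[[1L]]
    if (length(m)) m else NULL
  }

  m <- grab("^PC (aa|ae) C([0-9]+):([0-9]+)$")
  if (!is.null(m)) {
    return(new_analyte(nm, "PC", m[2L], m[3L], m[4L]))
  }
  m <- grab("^lysoPC a C([0-9]+):([0-9]+)$")
  if (!is.null(m)) {
    return(new_analyte(nm, "lysoPC", "a", m[2L], m[3L]))
  }
  m <- grab("^SM \\(OH\\) C([0-9]+):([0-9]+)$")
  if (!is.null(m)) {
    return(new_analyte(nm, "SM(OH)", "none", m[2L], m[3L]))
  }
  m <- grab("^SM C([0-9]+):([0-9]+)$")
  if (!is.null(m)) {
    return(new_analyte(nm, "SM", "none", m[2L], m[3L]))
  }
  m <- grab("^Cer C([0-9]+):([0-9]+)$")
  if (!is.null(m)) {
    return(new_analyte(nm, "CER", "none", m[2L], m[3L]))
  }
  # acylcarnitines: C0, C5:1, C5-DC, C5-M-DC, C16-OH, C16:2-OH, ...
  m <- grab("^C([0-9]+)(:([0-9]+))?(-(M-)?(OH|DC))?$")
  if (!is.null(m)) {
    moiety <- if (nzchar(m[7L])) m[7L] else "none"
    return(new_analyte(nm, "AC", "none", m[2L],
                       if (nzchar(m[4L])) m[4L] else "0", moiety))
  }
  stop_lipidcap("cannot parse analyte name '%s'", name)
}

new_analyte <- function(name, lipid_class, bond_type, n_carbons,
                        n_double_bonds, moiety = "none") {
  n_carbons <- as.integer(n_carbons)
  n_double_bonds <- as.integer(n_double_bonds)
  if (n_double_bonds > n_carbons) {
    stop_lipidcap("analyte '%s': %d double bonds exceed %d carbons",
                  name, n_double_bonds, n_carbons)
  }
  list(name = name, lipid_class = lipid_class, bond_type = bond_type,
       n_carbons = n_carbons, n_double_bonds = n_double_bonds,
       moiety = moiety)
}

# -- default panel ----------------------------------------------------------

p180_names <- function() {
  pc_aa <- paste0("PC aa C", c(
    "24:0", "26:0", "28:1", "30:0", "30:2", "32:0", "32:1", "32:2",
    "32:3", "34:1", "34:2", "34:3", "34:4", "36:0", "36:1", "36:2",
    "36:3", "36:4", "36:5", "36:6", "38:0", "38:1", "38:3", "38:4",
    "38:5", "38:6", "40:1", "40:2", "40:3", "40:4", "40:5", "40:6",
    "42:0", "42:1", "42:2", "42:4", "42:5", "42:6"))
  pc_ae <- paste0("PC ae C", c(
    "30:0", "30:1", "30:2", "32:1", "32:2", "34:0", "34:1", "34:2",
    "34:3", "36:0", "36:1", "36:2", "36:3", "36:4", "36:5", "38:0",
    "38:1", "38:2", "38:3", "38:4", "38:5", "38:6", "40:1", "40:2",
    "40:3", "40:4", "40:5", "40:6", "42:0", "42:1", "42:2", "42:3",
    "42:4", "42:5", "44:3", "44:4", "44:5", "44:6"))
  lyso <- paste0("lysoPC a C", c(
    "14:0", "16:0", "16:1", "17:0", "18:0", "18:1", "18:2", "20:3",
    "20:4", "24:0", "26:0", "26:1", "28:0", "28:1"))
  sm <- paste0("SM C", c(
    "16:0", "16:1", "18:0", "18:1", "20:2", "22:3", "24:0", "24:1",
    "26:0", "26:1"))
  smoh <- paste0("SM (OH) C", c("14:1", "16:1", "22:1", "22:2", "24:1"))
  ac <- c(
    "C0", "C2", "C3", "C3:1", "C3-OH", "C4", "C4:1", "C4-OH", "C5",
    "C5:1", "C5:1-DC", "C5-DC", "C5-M-DC", "C5-OH", "C6", "C6:1",
    "C7-DC", "C8", "C9", "C10", "C10:1", "C10:2", "C12", "C12:1",
    "C12-DC", "C14", "C14:1", "C14:1-OH", "C14:2", "C14:2-OH", "C16",
    "C16:1", "C16:1-OH", "C16:2", "C16:2-OH", "C16-OH", "C18", "C18:1",
    "C18:1-OH", "C18:2")
  c(pc_aa, pc_ae, lyso, sm, smoh, ac)
}

ceramide_names <- function() {
  paste0("Cer C", c("16:0", "18:0", "24:0", "24:1"))
}

# nominal assay LODs (uM) by class; overwritten by cohort-specific LODs
# when data are simulated, and user-overridable via a panel file
default_class_lod <- c(PC = 0.05, lysoPC = 0.05, SM = 0.02,
                       `SM(OH)` = 0.01, AC = 0.005, CER = 0.005)

#' Construct the default analyte panel registry
#'
#' The default registry holds the 145-analyte targeted panel (76 PC split
#' 38 diacyl / 38 acyl-alkyl, 14 lysoPC, 15 SM of which 5 hydroxy-SM, and
#' 40 acylcarnitines). The analyte names follow the kit nomenclature; the
#' exact membership is a reconstruction from the naming rules, and the
#' per-analyte LODs are nominal class-level values (LODs are data, not
#' method: the synthetic cohort generator replaces them with
#' cohort-specific values, and [read_panel()] accepts measured ones).
#'
#' @param include_ceramides Add the 4-ceramide extension (C16:0, C18:0,
#'   C24:0, C24:1) measured with a separate targeted assay but analyzed
#'   identically downstream.
#' @param lod Optional named numeric vector of per-analyte LODs (uM).
#' @return A `lipid_panel` data frame with columns `name`, `lipid_class`,
#'   `bond_type`, `n_carbons`, `n_double_bonds`, `moiety`, `lod`.
#' @export
default_panel <- function(include_ceramides = FALSE, lod = NULL) {
  nms <- p180_names()
  if (include_ceramides) nms <- c(nms, ceramide_names())
  parsed <- lapply(nms, parse_analyte_name)
  panel <- data.frame(
    name = vapply(parsed, `[[`, character(1L), "name"),
    lipid_class = vapply(parsed, `[[`, character(1L), "lipid_class"),
    bond_type = vapply(parsed, `[[`, character(1L), "bond_type"),
    n_carbons = vapply(parsed, `[[`, integer(1L), "n_carbons"),
    n_double_bonds = vapply(parsed, `[[`, integer(1L), "n_double_bonds"),
    moiety = vapply(parsed, `[[`, character(1L), "moiety"),
    stringsAsFactors = FALSE
  )
  panel$lod <- unname(default_class_lod[panel$lipid_class])
  if (!is.null(lod)) {
    idx <- match(names(lod), panel$name)
    if (anyNA(idx)) {
      stop_lipidcap("lod given for unknown analytes: %s",
                    paste(names(lod)[is.na(idx)], collapse = ", "))
    }
    panel$lod[idx] <- as.numeric(lod)
  }
  new_lipid_panel(panel)
}

#' Validate and class a panel registry
#'
#' @param panel Data frame with at least `name` and `lod` columns; missing
#'   annotation columns are filled by parsing the names.
#' @return A validated `lipid_panel`.
#' @export
new_lipid_panel <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("name", "lod") %in% names(panel)))
  if (!all(c("lipid_class", "bond_type", "n_carbons",
             "n_double_bonds", "moiety") %in% names(panel))) {
    parsed <- lapply(panel$name, parse_analyte_name)
    panel$lipid_class <- vapply(parsed, `[[`, character(1L), "lipid_class")
    panel$bond_type <- vapply(parsed, `[[`, character(1L), "bond_type")
    panel$n_carbons <- vapply(parsed, `[[`, integer(1L), "n_carbons")
    panel$n_double_bonds <- vapply(parsed, `[[`, integer(1L), "n_double_bonds")
    panel$moiety <- vapply(parsed, `[[`, character(1L), "moiety")
  }
  if (anyDuplicated(panel$name)) {
    stop_lipidcap("panel analyte names are not unique: %s",
                  paste(unique(panel$name[duplicated(panel$name)]),
                        collapse = ", "))
  }
  if (!all(panel$lipid_class %in% LIPID_CLASSES)) {
    stop_lipidcap("unknown lipid class: %s",
                  paste(setdiff(panel$lipid_class, LIPID_CLASSES),
                        collapse = ", "))
  }
  if (any(!is.finite(panel$lod) | panel$lod <= 0)) {
    stop_lipidcap("all panel LODs must be positive")
  }
  if (any(panel$n_double_bonds > panel$n_carbons)) {
    stop_lipidcap("double bonds exceed carbons for some analytes")
  }
  rownames(panel) <- NULL
  class(panel) <- c("lipid_panel", "data.frame")
  panel
}

#' Read a panel definition file
#'
#' The file is YAML: a list of entries with `name`, `lod` and optionally
#' `class` (to override the class inferred from the name).
#'
#' @param path Path to a panel YAML file.
#' @return A `lipid_panel`.
#' @export
read_panel <- function(path) {
  entries <- yaml::read_yaml(path)
  if (length(entries) == 0L) stop_lipidcap("panel file '%s' is empty", path)
  panel <- data.frame(
    name = vapply(entries, function(e) as.character(e$name), character(1L)),
    lod = vapply(entries, function(e) as.numeric(e$lod), numeric(1L)),
    stringsAsFactors = FALSE
  )
  panel <- new_lipid_panel(panel)
  cls <- vapply(entries, function(e) as.character(e$class %||% NA_character_),
                character(1L))
  override <- !is.na(cls)
  if (any(override)) {
    if (!all(cls[override] %in% LIPID_CLASSES)) {
      stop_lipidcap("unknown lipid class override: %s",
                    paste(setdiff(cls[override], LIPID_CLASSES),
                          collapse = ", "))
    }
    panel$lipid_class[override] <- cls[override]
  }
  panel
}

#' Class composition of a panel
#'
#' @param panel A `lipid_panel`.
#' @return Named integer vector of analyte counts per lipid class.
#' @export
class_counts <- function(panel) {
  stopifnot(inherits(panel, "lipid_panel"))
  tab <- table(factor(panel$lipid_class, levels = LIPID_CLASSES))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0L]
}

#' @export
print.lipid_panel <- function(x, ...) {
  cc <- class_counts(x)
  cat(sprintf("<lipid_panel> %d analytes: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(cc), cc), collapse = ", ")))
  invisible(x)
}
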