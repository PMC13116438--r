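#' Analyte panel: compound registry and internal-standard assignments
#'
#' A panel holds the native analytes monitored by the targeted LC-MS/MS
#' method and the isotopically labelled internal standards (IS) spiked into
#' every sample. Every downstream stage (response ratios, calibration,
#' quantitation, back-calculation) consults the panel for IS assignments,
#' drug classes, molecular weights and urinary excretion fractions.
#'
#' Natives are described by: `name`, `class` (one of opioid, stimulant,
#' benzodiazepine, synthetic_cathinone, dissociative, other), `mw`
#' (molecular weight, g/mol), `role` (parent, metabolite or other), `parent`
#' (the parent compound for metabolites, used for molecular-weight
#' correction during consumption back-calculation), `excretion_fraction`
#' (fraction of a dose excreted in urine as this biomarker, in (0, 1]) and
#' `is_name` (the assigned labelled standard). SRM transition values
#' (`q1`, `q3_quant`, `q3_confirm`, `ce1`, `ce2`) are carried as metadata
#' only and never computed from structure.
#'
#' @param natives tibble of native analytes (see Details).
#' @param standards tibble of labelled internal standards with columns
#'   `name` and `analog_of` (the native the label mimics, `NA` for pure
#'   surrogates) plus optional transition metadata.
#' @return An object of class `wbe_panel`: a validated list with elements
#'   `natives` and `standards`.
#' @seealso [read_panel()], [default_panel()], [resolve_is()],
#'   [class_counts()]
#' @export
new_panel <- function(natives, standards) {
  panel <- structure(list(natives = as_tibble(natives),
                          standards = as_tibble(standards)),
                     class = "wbe_panel")
  validate_panel(panel)
}

#' Validate a panel against its structural invariants
#'
#' Checks name uniqueness across natives and standards, positive molecular
#' weights, excretion fractions in (0, 1], resolvable internal-standard
#' assignments, and that every metabolite's `parent` names a panel member
#' with role `parent`. Errors name the offending compound.
#'
#' @param panel a `wbe_panel`.
#' @return The panel, invisibly unchanged, if valid.
#' @export
validate_panel <- function(panel) {
  nat <- panel$natives
  std <- panel$standards
  req <- c("name", "class", "mw", "role", "is_name")
  missing_cols <- setdiff(req, names(nat))
  if (length(missing_cols) > 0) {
    abort(paste0("panel natives lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(c("name") %in% names(std))) {
    abort("panel standards lack a 'name' column")
  }
  all_names <- c(nat$name, std$name)
  if (anyDuplicated(all_names)) {
    abort(paste0("duplicate panel names: ",
                 paste(unique(all_names[duplicated(all_names)]),
                       collapse = ", ")))
  }
  bad_class <- setdiff(unique(nat$class), WBE_CLASSES)
  if (length(bad_class) > 0) {
    abort(paste0("unknown drug class(es): ", paste(bad_class, collapse = ", ")))
  }
  bad_mw <- nat$name[is.na(nat$mw) | nat$mw <= 0]
  if (length(bad_mw) > 0) {
    abort(paste0("missing or non-positive molecular weight for: ",
                 paste(bad_mw, collapse = ", ")))
  }
  if ("excretion_fraction" %in% names(nat)) {
    ef <- nat$excretion_fraction
    bad_ef <- nat$name[!is.na(ef) & (ef <= 0 | ef > 1)]
    if (length(bad_ef) > 0) {
      abort(paste0("excretion_fraction outside (0, 1] for: ",
                   paste(bad_ef, collapse = ", ")))
    }
  }
  dangling_is <- setdiff(nat$is_name[!is.na(nat$is_name)], std$name)
  if (length(dangling_is) > 0) {
    abort(paste0("internal standard(s) assigned but not declared: ",
                 paste(dangling_is, collapse = ", ")))
  }
  no_is <- nat$name[is.na(nat$is_name)]
  if (length(no_is) > 0) {
    abort(paste0("native(s) without an internal-standard assignment: ",
                 paste(no_is, collapse = ", ")))
  }
  metab <- nat[nat$role == "metabolite" & !is.na(nat$parent), , drop = FALSE]
  if (nrow(metab) > 0) {
    parents <- nat$name[nat$role == "parent"]
    bad_parent <- metab$name[!(metab$parent %in% parents)]
    if (length(bad_parent) > 0) {
      abort(paste0("metabolite(s) whose parent is not a panel parent: ",
                   paste(bad_parent, collapse = ", ")))
    }
  }
  if ("analog_of" %in% names(std)) {
    known <- std$analog_of[!is.na(std$analog_of)]
    bad_analog <- setdiff(known, nat$name)
    if (length(bad_analog) > 0) {
      abort(paste0("standard labelled analog of unknown native: ",
                   paste(bad_analog, collapse = ", ")))
    }
  }
  invisible(panel)
}

#' Read a panel from a compound-table CSV
#'
#' One row per species. Native analytes use `role` in
#' `{parent, metabolite, other}`; labelled standards use
#' `role = "internal_standard"`, with the `parent` column holding the native
#' they are the labelled analog of (blank for pure surrogates).
#'
#' Columns: `name, class, mw, role, parent, excretion_fraction, is_name,
#' q1, q3_quant, q3_confirm, ce1, ce2`.
#'
#' @param path CSV file path.
#' @param delim `"comma"` or `"tab"`.
#' @return A validated `wbe_panel`.
#' @export
read_panel <- function(path, delim = c("comma", "tab")) {
  delim <- match.arg(delim)
  tbl <- wbe_read_delim(path, delim,
                        col_types = readr::cols(
                          name = readr::col_character(),
                          class = readr::col_character(),
                          mw = readr::col_double(),
                          role = readr::col_character(),
                          parent = readr::col_character(),
                          excretion_fraction = readr::col_double(),
                          is_name = readr::col_character(),
                          .default = readr::col_double()))
  is_std <- tbl$role == "internal_standard"
  standards <- tbl[is_std, , drop = FALSE] %>%
    rename(analog_of = "parent") %>%
    select(-dplyr::any_of(c("class", "role", "excretion_fraction",
                            "is_name", "mw")))
  natives <- tbl[!is_std, , drop = FALSE]
  new_panel(natives, standards)
}

#' Write a panel back to the CSV layout `read_panel()` accepts
#'
#' @param panel a `wbe_panel`.
#' @param path output CSV path.
#' @param delim `"comma"` or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, delim = c("comma", "tab")) {
  delim <- match.arg(delim)
  std <- panel$standards %>% rename(parent = "analog_of")
  std$class <- NA_character_
  std$mw <- NA_real_
  std$role <- "internal_standard"
  std$excretion_fraction <- NA_real_
  std$is_name <- NA_character_
  cols <- c("name", "class", "mw", "role", "parent", "excretion_fraction",
            "is_name", "q1", "q3_quant", "q3_confirm", "ce1", "ce2")
  out <- bind_rows(panel$natives, std)
  for (cl in setdiff(cols, names(out))) out[[cl]] <- NA_real_
  out <- out[, cols]
  if (delim == "comma") readr::write_csv(out, path, na = "")
  else readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' The packaged default analyte panel
#'
#' 52 native analytes (opioids 15, stimulants 11, benzodiazepines 5,
#' synthetic cathinones 5, dissociatives 2, other pharmaceuticals and
#' metabolites 14) and 22 isotopically labelled internal standards.
#' Natives without a structurally matched labelled standard are assigned the
#' nearest-class surrogate; the mapping is data in
#' `extdata/default_panel.csv`, not code. Excretion fractions are
#' literature-shaped defaults intended to be replaced with values curated
#' for the study population; Q1 m/z entries are protonated-molecular-weight
#' placeholders and product-ion/collision-energy fields are left blank until
#' instrument values are transcribed.
#'
#' @return A validated `wbe_panel`.
#' @export
default_panel <- function() {
  path <- system.file("extdata", "default_panel.csv", package = "wbequant",
                      mustWork = TRUE)
  read_panel(path)
}

#' Look up the internal standard assigned to a native analyte
#'
#' Several natives may share one surrogate standard; every native resolves
#' to exactly one.
#'
#' @param panel a `wbe_panel`.
#' @param compound native analyte name.
#' @return One-row tibble describing the standard.
#' @export
resolve_is <- function(panel, compound) {
  nat <- panel$natives[panel$natives$name == compound, , drop = FALSE]
  if (nrow(nat) == 0) {
    abort(paste0("unknown compound: ", compound))
  }
  panel$standards[panel$standards$name == nat$is_name[1], , drop = FALSE]
}

#' Count native analytes per drug class
#'
#' Counts cover natives only (labelled standards are not classed) and always
#' sum to the number of natives; absent classes count zero.
#'
#' @param panel a `wbe_panel`.
#' @return Named integer vector over the closed class taxonomy.
#' @export
class_counts <- function(panel) {
  counts <- table(factor(panel$natives$class, levels = WBE_CLASSES))
  setNames(as.integer(counts), WBE_CLASSES)
}

#' @export
print.wbe_panel <- function(x, ...) {
  cc <- class_counts(x)
  cat("<wbe_panel> ", nrow(x$natives), " natives, ",
      nrow(x$standards), " internal standards\n", sep = "")
  cat(paste0("  ", names(cc), ": ", cc, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' Pharmacokinetic constants for consumption back-calculation
#'
#' Assembles, per biomarker, the urinary excretion fraction and the
#' parent/metabolite molecular weights needed by [consumption_rate()].
#'
#' @param panel a `wbe_panel`.
#' @return Tibble with columns `compound`, `parent_compound`,
#'   `measured_is_metabolite`, `excretion_fraction`, `mw_parent`,
#'   `mw_metabolite`.
#' @export
pk_table <- function(panel) {
  nat <- panel$natives
  mw_of <- setNames(nat$mw, nat$name)
  tibble(
    compound = nat$name,
    parent_compound = ifelse(nat$role == "metabolite" & !is.na(nat$parent),
                             nat$parent, nat$name),
    measured_is_metabolite = nat$role == "metabolite" & !is.na(nat$parent),
    excretion_fraction = if ("excretion_fraction" %in% names(nat)) {
      nat$excretion_fraction
    } else NA_real_,
    mw_parent = unname(mw_of[ifelse(nat$role == "metabolite" &
                                      !is.na(nat$parent),
                                    nat$parent, nat$name)]),
    mw_metabolite = nat$mw
  )
}
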