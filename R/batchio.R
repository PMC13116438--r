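#' Tabular input/output for the quantitation workflow
#'
#' Readers validate every row against the type invariants of the workflow
#' (non-negative areas, positive noise, sample-type-specific required
#' fields) and report offending row numbers. Writers emit a fixed column
#' order so identical inputs produce byte-identical files. Censored values
#' are encoded as a `status` column plus a numeric bound, never as text
#' inside a numeric column.
#'
#' @name batchio
NULL

wbe_read_delim <- function(path, delim = c("comma", "tab"), col_types) {
  delim <- match.arg(delim)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  reader <- if (delim == "comma") readr::read_csv else readr::read_tsv
  tbl <- suppressWarnings(reader(path, col_types = col_types,
                                 progress = FALSE,
                                 na = c("", "NA")))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0("parse error in ", path, " at row(s) ",
                 paste(unique(probs$row), collapse = ", "),
                 " (", probs$expected[1], " expected, got '",
                 probs$actual[1], "')"))
  }
  tbl
}

assert_columns <- function(tbl, required, what) {
  miss <- setdiff(required, names(tbl))
  if (length(miss) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  invisible(tbl)
}

row_error <- function(bad, msg) {
  if (any(bad, na.rm = TRUE)) {
    abort(paste0(msg, " at row(s) ",
                 paste(head(which(bad), 10), collapse = ", ")))
  }
}

#' Read a long-format peak-area table
#'
#' One row per (sample, compound, transition) as exported by quantitation
#' software. Required columns: `sample_id`, `compound`, `transition`
#' (`quant` or `confirm`), `area`; optional `height` and `noise_sd`
#' (baseline noise standard deviation near the peak, used for
#' signal-to-noise LOD/LOQ work). Unknown compound names are preserved and
#' validated later against the panel.
#'
#' @param path delimited text file with a header row.
#' @param delim `"comma"` or `"tab"`.
#' @return Tibble of validated peak records.
#' @export
read_peak_table <- function(path, delim = c("comma", "tab")) {
  tbl <- wbe_read_delim(path, delim, col_types = readr::cols(
    sample_id = readr::col_character(),
    compound = readr::col_character(),
    transition = readr::col_character(),
    .default = readr::col_double()))
  assert_columns(tbl, c("sample_id", "compound", "transition", "area"),
                 "peak table")
  if (!"height" %in% names(tbl)) tbl$height <- NA_real_
  if (!"noise_sd" %in% names(tbl)) tbl$noise_sd <- NA_real_
  validate_peaks(tbl)
}

#' Validate peak records against their invariants
#'
#' @param tbl tibble shaped like [read_peak_table()] output.
#' @return The validated tibble.
#' @export
validate_peaks <- function(tbl) {
  row_error(!(tbl$transition %in% c("quant", "confirm")),
            "transition must be 'quant' or 'confirm'")
  row_error(is.na(tbl$area) | tbl$area < 0, "area must be >= 0")
  row_error(!is.na(tbl$height) & tbl$height < 0, "height must be >= 0")
  row_error(!is.na(tbl$noise_sd) & tbl$noise_sd <= 0,
            "noise_sd must be > 0 when present")
  tbl
}

#' Read a sample manifest
#'
#' Required columns: `sample_id`, `sample_type` (calibrant, blank,
#' qc_unspiked, qc_spiked, field, spike_before, spike_after). Optional:
#' `nominal_ngml` (spike-mix concentration, required for calibrants and
#' spiked QCs), `mass_g` (gravimetric sample mass, required for field
#' samples), `density_g_per_ml` (defaults to 1.0), `site_id`,
#' `collected_on` (ISO-8601 date), `replicate_group` (required for
#' spike-before/spike-after recovery samples) and `sorbent`.
#'
#' @inheritParams read_peak_table
#' @return Tibble of validated sample metadata.
#' @export
read_manifest <- function(path, delim = c("comma", "tab")) {
  tbl <- wbe_read_delim(path, delim, col_types = readr::cols(
    sample_id = readr::col_character(),
    sample_type = readr::col_character(),
    site_id = readr::col_character(),
    collected_on = readr::col_date(),
    replicate_group = readr::col_character(),
    sorbent = readr::col_character(),
    .default = readr::col_double()))
  assert_columns(tbl, c("sample_id", "sample_type"), "manifest")
  defaults <- list(nominal_ngml = NA_real_, mass_g = NA_real_,
                   density_g_per_ml = NA_real_, site_id = NA_character_,
                   collected_on = as.Date(NA), replicate_group = NA_character_,
                   sorbent = NA_character_)
  for (cl in names(defaults)) {
    if (!cl %in% names(tbl)) tbl[[cl]] <- defaults[[cl]]
  }
  tbl$density_g_per_ml[is.na(tbl$density_g_per_ml)] <- 1.0
  validate_manifest(tbl)
}

#' Validate sample metadata against sample-type requirements
#'
#' @param tbl tibble shaped like [read_manifest()] output.
#' @return The validated tibble.
#' @export
validate_manifest <- function(tbl) {
  row_error(!(tbl$sample_type %in% WBE_SAMPLE_TYPES),
            "unknown sample_type")
  row_error(duplicated(tbl$sample_id), "duplicate sample_id")
  needs_nominal <- tbl$sample_type %in% c("calibrant", "qc_spiked")
  row_error(needs_nominal & (is.na(tbl$nominal_ngml) | tbl$nominal_ngml < 0),
            "calibrant/qc_spiked samples require nominal_ngml >= 0")
  row_error(tbl$sample_type == "field" &
              (is.na(tbl$mass_g) | tbl$mass_g <= 0),
            "field samples require mass_g > 0")
  row_error(!is.na(tbl$mass_g) & tbl$mass_g <= 0, "mass_g must be > 0")
  row_error(tbl$density_g_per_ml <= 0, "density_g_per_ml must be > 0")
  row_error(tbl$sample_type %in% c("spike_before", "spike_after") &
              is.na(tbl$replicate_group),
            "spike_before/spike_after samples require replicate_group")
  tbl
}

#' Read site metadata (population served and daily flow)
#'
#' Required columns: `site_id`, `population` (persons), `flow_l_per_day`
#' (litres/day); optional `measured_on` date for per-date flow records.
#'
#' @inheritParams read_peak_table
#' @return Tibble of validated site records.
#' @export
read_sites <- function(path, delim = c("comma", "tab")) {
  tbl <- wbe_read_delim(path, delim, col_types = readr::cols(
    site_id = readr::col_character(),
    measured_on = readr::col_date(),
    .default = readr::col_double()))
  assert_columns(tbl, c("site_id", "population", "flow_l_per_day"), "sites")
  validate_sites(tbl)
}

#' Validate site metadata
#' @param tbl tibble shaped like [read_sites()] output.
#' @return The validated tibble.
#' @export
validate_sites <- function(tbl) {
  row_error(is.na(tbl$population) | tbl$population <= 0,
            "population must be > 0")
  row_error(is.na(tbl$flow_l_per_day) | tbl$flow_l_per_day <= 0,
            "flow_l_per_day must be > 0")
  tbl
}

wbe_write_delim <- function(tbl, path, columns, delim = c("comma", "tab")) {
  delim <- match.arg(delim)
  for (cl in setdiff(columns, names(tbl))) tbl[[cl]] <- NA
  tbl <- tbl[, columns]
  if (delim == "comma") readr::write_csv(tbl, path, na = "")
  else readr::write_tsv(tbl, path, na = "")
  invisible(path)
}

RESULT_COLUMNS <- c("batch_id", "sample_id", "compound", "extract_conc_ngml",
                    "sample_conc_ngl", "status", "lod_ngl", "loq_ngl",
                    "qc_pass")

RATE_COLUMNS <- c("site_id", "collected_on", "compound", "parent_compound",
                  "excretion_mg_day_1000", "consumption_mg_day_1000",
                  "status")

RECOVERY_COLUMNS <- c("compound", "sorbent", "recovery_pct", "rsd_pct",
                      "n_before", "n_after")

#' Write workflow result tables deterministically
#'
#' Column order is fixed per table kind; the censoring status travels as its
#' own column next to the numeric value/bound so downstream numeric
#' summaries stay well defined. Identical inputs yield byte-identical files.
#'
#' @param tbl a measurements, rates or recovery tibble.
#' @param path output file path.
#' @param delim `"comma"` or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(tbl, path, delim = c("comma", "tab")) {
  wbe_write_delim(tbl, path, RESULT_COLUMNS, delim)
}

#' @rdname write_results
#' @export
write_rates <- function(tbl, path, delim = c("comma", "tab")) {
  wbe_write_delim(tbl, path, RATE_COLUMNS, delim)
}

#' @rdname write_results
#' @export
write_recovery <- function(tbl, path, delim = c("comma", "tab")) {
  wbe_write_delim(tbl, path, RECOVERY_COLUMNS, delim)
}

#' Read back a results table written by [write_results()]
#'
#' @inheritParams read_peak_table
#' @return Tibble of measurements.
#' @export
read_results <- function(path, delim = c("comma", "tab")) {
  tbl <- wbe_read_delim(path, delim, col_types = readr::cols(
    batch_id = readr::col_character(),
    sample_id = readr::col_character(),
    compound = readr::col_character(),
    status = readr::col_character(),
    qc_pass = readr::col_logical(),
    .default = readr::col_double()))
  assert_columns(tbl, RESULT_COLUMNS, "results")
  row_error(!(tbl$status %in% WBE_STATUSES), "unknown status")
  tbl
}
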