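#' Run the full quantitation workflow on one batch
#'
#' Wires the stages in order: calibration fitting, LOD/LOQ sensitivity
#' (when calibrant peaks carry heights and noise), sample quantitation,
#' QC gating, and — when site metadata are supplied — excretion and
#' consumption back-calculation. Every exclusion and gate decision is
#' recorded as one auditable log line. The pipeline is deterministic:
#' identical inputs produce identical outputs.
#'
#' @param peaks,manifest,panel batch inputs (tibbles / `wbe_panel`).
#' @param sites optional sites tibble; enables back-calculation.
#' @param weighting,min_r2 calibration options (see [fit_calibration()]).
#' @param extract_volume_ml final extract volume, mL.
#' @param substitution censoring substitution policy.
#' @param state optional `wbe_lodloq_state` carried across runs.
#' @param batch_id,run_id labels for this batch/run.
#' @return List of class `wbe_run`: `fits`, `sensitivity`, `measurements`,
#'   `qc`, `rates` (or `NULL`), `state`, `log` (character vector).
#' @export
run_pipeline <- function(peaks, manifest, panel, sites = NULL,
                         weighting = "1/x", min_r2 = 0.995,
                         extract_volume_ml = 0.5,
                         substitution = "half_lod",
                         state = new_lodloq_state(),
                         batch_id = "batch1", run_id = batch_id) {
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  ratios <- withCallingHandlers(
    response_ratios(peaks, manifest, panel, sample_types = "calibrant"),
    warning = function(w) {
      note("calibrate: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  fits <- withCallingHandlers(
    fit_calibrations(ratios, weighting = weighting, min_r2 = min_r2),
    warning = function(w) {
      note("calibrate: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  for (cmp in fits$compound[!fits$accepted]) {
    note("calibrate: curve for ", cmp, " rejected (r2 below ", min_r2,
         " or non-positive slope); compound not quantifiable")
  }

  cal_ids <- manifest$sample_id[manifest$sample_type == "calibrant"]
  has_sn <- any(!is.na(peaks$height[peaks$sample_id %in% cal_ids]) &
                  !is.na(peaks$noise_sd[peaks$sample_id %in% cal_ids]))
  sens <- NULL
  if (has_sn) {
    sv <- withCallingHandlers(
      sensitivity_evaluate(peaks, manifest, state = state, run_id = run_id,
                           compounds = panel$natives$name),
      warning = function(w) {
        note("sensitivity: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    sens <- sv$records
    state <- sv$state
    for (i in which(is.na(sens$lod_run))) {
      note("sensitivity: LOD not determined this run for ",
           sens$compound[i])
    }
  } else {
    note("sensitivity: calibrant peaks carry no height/noise; ",
         "LOD/LOQ stage skipped")
  }

  measurements <- withCallingHandlers(
    quantify_batch(peaks, manifest, fits, sensitivity = sens,
                   panel = panel, extract_volume_ml = extract_volume_ml,
                   batch_id = batch_id),
    warning = function(w) {
      note("quantify: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  qc <- NULL
  if (any(manifest$sample_type == "qc_spiked")) {
    qc <- qc_evaluate(measurements, manifest)
    for (i in which(!qc$accuracy_pass)) {
      note("qc: accuracy ", round(qc$accuracy_pct[i], 1), "% for ",
           qc$compound[i], " outside [80, 120]%")
    }
    for (i in which(!qc$precision_pass)) {
      note("qc: RSD ", round(qc$rsd_pct[i], 1), "% for ", qc$compound[i],
           " not below 20%")
    }
    if (!all(qc$blank_clean)) note("qc: method blank not clean")
    measurements <- set_qc_flag(measurements, qc)
    if (!all(measurements$qc_pass)) {
      note("qc: batch ", batch_id,
           " flagged qc_pass = FALSE (measurements retained)")
    }
  } else {
    note("qc: no spiked QC samples in batch; qc_pass left NA")
  }

  rates <- NULL
  if (!is.null(sites)) {
    rates <- rates_for_dataset(measurements, manifest, sites, panel,
                               substitution = substitution)
    n_sub <- sum(rates$status == "below_lod")
    if (n_sub > 0) {
      note("backcalc: ", n_sub, " censored measurement(s) entered rates ",
           "under the '", substitution, "' substitution policy")
    }
  }

  structure(list(fits = fits, sensitivity = sens,
                 measurements = measurements, qc = qc, rates = rates,
                 state = state, log = log),
            class = "wbe_run")
}

#' @export
print.wbe_run <- function(x, ...) {
  cat("<wbe_run>\n")
  cat("  calibrations: ", nrow(x$fits), " (",
      sum(x$fits$accepted), " accepted)\n", sep = "")
  if (!is.null(x$sensitivity)) {
    cat("  sensitivity records:", nrow(x$sensitivity), "\n")
  }
  cat("  measurements:", nrow(x$measurements), "\n")
  if (!is.null(x$qc)) {
    cat("  qc: ", sum(x$qc$accuracy_pass & x$qc$precision_pass), "/",
        nrow(x$qc), " compounds pass\n", sep = "")
  }
  if (!is.null(x$rates)) cat("  rate records:", nrow(x$rates), "\n")
  cat("  log lines:", length(x$log), "\n")
  invisible(x)
}

#' File-based pipeline front end
#'
#' Reads the CSV artifacts, runs [run_pipeline()], and writes
#' `results.csv`, `rates.csv` (when sites are given), `qc_report.csv`,
#' `fits.csv`, `sensitivity.csv` and `log.txt` into `outdir`.
#'
#' @param peaks_path,manifest_path,panel_path,sites_path input file paths
#'   (`sites_path` optional).
#' @param outdir output directory (created if absent).
#' @param state_path optional LOD/LOQ reference state JSON, read before and
#'   rewritten after the run.
#' @param delim `"comma"` or `"tab"`.
#' @param ... passed to [run_pipeline()].
#' @return The `wbe_run`, invisibly.
#' @export
run_pipeline_files <- function(peaks_path, manifest_path, panel_path,
                               sites_path = NULL, outdir = ".",
                               state_path = NULL,
                               delim = c("comma", "tab"), ...) {
  delim <- match.arg(delim)
  peaks <- read_peak_table(peaks_path, delim)
  manifest <- read_manifest(manifest_path, delim)
  panel <- read_panel(panel_path, delim)
  sites <- if (!is.null(sites_path)) read_sites(sites_path, delim)
  state <- if (!is.null(state_path)) read_lodloq_state(state_path)
  else new_lodloq_state()
  run <- run_pipeline(peaks, manifest, panel, sites = sites,
                      state = state, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_results(run$measurements, file.path(outdir, "results.csv"), delim)
  readr::write_csv(run$fits, file.path(outdir, "fits.csv"), na = "")
  if (!is.null(run$sensitivity)) {
    readr::write_csv(run$sensitivity,
                     file.path(outdir, "sensitivity.csv"), na = "")
  }
  if (!is.null(run$qc)) {
    readr::write_csv(run$qc, file.path(outdir, "qc_report.csv"), na = "")
  }
  if (!is.null(run$rates)) {
    write_rates(run$rates, file.path(outdir, "rates.csv"), delim)
  }
  if (!is.null(state_path)) write_lodloq_state(run$state, state_path)
  writeLines(run$log, file.path(outdir, "log.txt"))
  invisible(run)
}
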