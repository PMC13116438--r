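#' Extract-to-sample concentration factor
#'
#' A gravimetrically weighed aliquot of `mass_g` grams at density
#' `density_g_per_ml` g/mL corresponds to `mass_g / density / 1000` litres
#' of wastewater; the SPE eluate is reconstituted to `extract_volume_ml`
#' millilitres (default 0.5 mL, the final reconstitution volume — the
#' interim evaporation endpoint is superseded by the dilution). A
#' concentration measured in the extract (ng/mL) times this factor is the
#' wastewater concentration in ng/L.
#'
#' @param mass_g gravimetric sample mass, grams.
#' @param density_g_per_ml wastewater density, g/mL (default 1.0).
#' @param extract_volume_ml final extract volume, mL (default 0.5).
#' @return Dimensionless factor ng/mL (extract) -> ng/L (wastewater).
#' @export
concentration_factor <- function(mass_g, density_g_per_ml = 1.0,
                                 extract_volume_ml = 0.5) {
  if (any(is.na(mass_g) | mass_g <= 0)) abort("mass_g must be > 0")
  if (any(is.na(density_g_per_ml) | density_g_per_ml <= 0)) {
    abort("density_g_per_ml must be > 0")
  }
  if (any(is.na(extract_volume_ml) | extract_volume_ml <= 0)) {
    abort("extract_volume_ml must be > 0")
  }
  sample_volume_l <- mass_g / density_g_per_ml / 1000
  extract_volume_ml / sample_volume_l
}

#' Quantify a batch of samples against accepted calibrations
#'
#' Forms isotope-dilution response ratios for the requested sample types,
#' inverts each compound's accepted calibration to an extract
#' concentration, converts field samples to wastewater units (ng/L) with
#' the per-sample [concentration_factor()], propagates the reported LOD/LOQ
#' to the same units, and censors. Compounds without an accepted
#' calibration are reported as `not_quantifiable`. Negative inverse
#' predictions are censored `below_lod` with the wastewater value reported
#' as 0. Field samples without a gravimetric mass are an error listing the
#' offending samples.
#'
#' @param peaks,manifest,panel batch inputs.
#' @param fits calibration table from [fit_calibrations()].
#' @param sensitivity optional records tibble from [sensitivity_evaluate()]
#'   (uses `lod_reported`/`loq_reported`, ng/mL in extract units).
#' @param extract_volume_ml final extract volume, mL.
#' @param batch_id label stamped on every measurement.
#' @param sample_types which manifest types to quantify.
#' @return Measurements tibble: `batch_id`, `sample_id`, `compound`,
#'   `extract_conc_ngml`, `sample_conc_ngl`, `status`, `lod_ngl`,
#'   `loq_ngl`, `qc_pass` (filled by [set_qc_flag()], `NA` until then).
#' @export
quantify_batch <- function(peaks, manifest, fits, sensitivity = NULL,
                           panel, extract_volume_ml = 0.5,
                           batch_id = "batch1",
                           sample_types = c("field", "blank", "qc_unspiked",
                                            "qc_spiked")) {
  keep <- manifest[manifest$sample_type %in% sample_types, , drop = FALSE]
  missing_mass <- keep$sample_id[keep$sample_type == "field" &
                                   (is.na(keep$mass_g) | keep$mass_g <= 0)]
  if (length(missing_mass) > 0) {
    abort(paste0("field sample(s) missing mass_g: ",
                 paste(missing_mass, collapse = ", ")))
  }
  ratios <- response_ratios(peaks, manifest, panel,
                            sample_types = sample_types)
  lims <- if (!is.null(sensitivity)) {
    sensitivity[, c("compound", "lod_reported", "loq_reported")]
  } else {
    tibble(compound = character(0), lod_reported = numeric(0),
           loq_reported = numeric(0))
  }
  out <- ratios %>%
    left_join(fits, by = "compound") %>%
    left_join(lims, by = "compound") %>%
    left_join(keep[, c("sample_id", "sample_type", "mass_g",
                       "density_g_per_ml")], by = "sample_id")
  factor <- rep(NA_real_, nrow(out))
  has_mass <- !is.na(out$mass_g) & out$mass_g > 0
  if (any(has_mass)) {
    factor[has_mass] <- concentration_factor(
      out$mass_g[has_mass], out$density_g_per_ml[has_mass],
      extract_volume_ml)
  }
  quantifiable <- !is.na(out$accepted) & out$accepted
  extract_conc <- rep(NA_real_, nrow(out))
  extract_conc[quantifiable] <-
    (out$ratio[quantifiable] - out$intercept[quantifiable]) /
    out$slope[quantifiable]
  status <- rep("not_quantifiable", nrow(out))
  status[quantifiable] <- censor_status(
    extract_conc[quantifiable],
    out$lod_reported[quantifiable],
    out$loq_reported[quantifiable])
  sample_conc <- extract_conc * factor
  sample_conc[quantifiable & extract_conc < 0 & !is.na(factor)] <- 0
  tibble(
    batch_id = batch_id,
    sample_id = out$sample_id,
    compound = out$compound,
    extract_conc_ngml = extract_conc,
    sample_conc_ngl = sample_conc,
    status = status,
    lod_ngl = out$lod_reported * factor,
    loq_ngl = out$loq_reported * factor,
    qc_pass = NA
  )
}

#' Evaluate batch quality-control acceptance
#'
#' Accuracy per compound is 100 x mean(measured extract concentration) /
#' nominal over the spiked-QC replicates; precision is the replicate RSD
#' (100 x sd/mean). A compound passes accuracy within the inclusive
#' \[80, 120\]% band ("within +/-20% of the expected value") and precision
#' strictly below 20% RSD. `blank_clean` records whether every blank
#' measurement censored below the LOD.
#'
#' @param measurements output of [quantify_batch()] including `qc_spiked`
#'   (and ideally `blank`) samples.
#' @param manifest the batch manifest (source of nominal concentrations).
#' @param accuracy_band inclusive accuracy limits, percent.
#' @param rsd_limit exclusive RSD limit, percent.
#' @return Tibble of class `wbe_qc_report`: `batch_id`, `compound`,
#'   `accuracy_pct`, `rsd_pct`, `n_replicates`, `accuracy_pass`,
#'   `precision_pass`, `blank_clean`.
#' @export
qc_evaluate <- function(measurements, manifest,
                        accuracy_band = c(80, 120), rsd_limit = 20) {
  qc_meta <- manifest[manifest$sample_type == "qc_spiked", , drop = FALSE]
  if (any(is.na(qc_meta$nominal_ngml) | qc_meta$nominal_ngml == 0)) {
    abort("qc_spiked samples require a nonzero nominal_ngml")
  }
  qc <- measurements[measurements$sample_id %in% qc_meta$sample_id, ,
                     drop = FALSE] %>%
    left_join(qc_meta[, c("sample_id", "nominal_ngml")], by = "sample_id")
  if (nrow(qc) == 0) abort("no qc_spiked measurements in this batch")
  n_rep <- table(qc$compound)
  if (any(n_rep < 2)) {
    abort(paste0("RSD requires >= 2 QC replicates; offending compound(s): ",
                 paste(names(n_rep)[n_rep < 2], collapse = ", ")))
  }
  blank_ids <- manifest$sample_id[manifest$sample_type == "blank"]
  blanks <- measurements[measurements$sample_id %in% blank_ids, ,
                         drop = FALSE]
  blank_clean <- nrow(blanks) == 0 || all(blanks$status == "below_lod")
  report <- qc %>%
    group_by(batch_id = .data$batch_id, compound = .data$compound) %>%
    summarise(
      accuracy_pct = 100 * mean(.data$extract_conc_ngml) /
        .data$nominal_ngml[1],
      rsd_pct = 100 * sd(.data$extract_conc_ngml) /
        mean(.data$extract_conc_ngml),
      n_replicates = n(),
      .groups = "drop") %>%
    mutate(
      accuracy_pass = .data$accuracy_pct >= accuracy_band[1] &
        .data$accuracy_pct <= accuracy_band[2],
      precision_pass = .data$rsd_pct < rsd_limit,
      blank_clean = blank_clean)
  class(report) <- c("wbe_qc_report", class(report))
  report
}

#' Flag a batch's measurements with the QC outcome
#'
#' A failed QC (any compound failing accuracy or precision, or a dirty
#' blank) flags every measurement in the batch (`qc_pass = FALSE`) but
#' deletes nothing — the data remain available for inspection.
#'
#' @param measurements output of [quantify_batch()].
#' @param qc_report output of [qc_evaluate()].
#' @return Measurements with `qc_pass` filled in.
#' @export
set_qc_flag <- function(measurements, qc_report) {
  pass <- all(qc_report$accuracy_pass) && all(qc_report$precision_pass) &&
    all(qc_report$blank_clean)
  measurements$qc_pass <- pass
  measurements
}

#' Build a randomized injection queue
#'
#' Calibrants, blanks and QCs are randomly interleaved among sample
#' extracts: a deterministic permutation of all sample ids under the given
#' seed. The caller's RNG state is untouched.
#'
#' @param sample_ids character vector (each id injected exactly once).
#' @param seed integer seed.
#' @return Permuted character vector.
#' @export
build_run_queue <- function(sample_ids, seed) {
  with_seed(seed, sample_ids[sample.int(length(sample_ids))])
}

#' Summarize concentrations under a censoring substitution policy
#'
#' Below-LOD values enter summaries as LOD/2 by default; `zero`,
#' `lod_sqrt2` (LOD divided by sqrt(2)) and `exclude` are selectable.
#' Between-LOD-and-LOQ values are used as measured.
#'
#' @param conc concentrations (any unit, shared with `lod`).
#' @param status censor statuses from [censor_status()].
#' @param lod per-value detection limits (same unit as `conc`).
#' @param policy substitution policy.
#' @return The substituted values (`NA` where excluded or not
#'   quantifiable), same length as `conc` except under `exclude`.
#' @export
substitute_censored <- function(conc, status, lod,
                                policy = c("half_lod", "zero", "lod_sqrt2",
                                           "exclude")) {
  policy <- match.arg(policy)
  out <- conc
  out[status == "not_quantifiable"] <- NA_real_
  below <- status == "below_lod"
  out[below] <- switch(policy,
                       half_lod = lod[below] / 2,
                       zero = 0,
                       lod_sqrt2 = lod[below] / sqrt(2),
                       exclude = NA_real_)
  if (policy == "exclude") out <- out[!below]
  out
}
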