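#' Signal-to-noise series from calibrant peaks
#'
#' S/N = peak height / baseline noise standard deviation, per compound per
#' calibrant level. Replicate injections of the same level are averaged.
#' Compounds without `noise_sd` values are excluded with a warning; a zero
#' `noise_sd` is a division guard error (validators normally reject it
#' earlier).
#'
#' @param peaks peak tibble carrying `height` and `noise_sd`.
#' @param manifest sample manifest; only `calibrant` rows are used.
#' @param compounds optional restriction to these analytes (e.g. panel
#'   natives, so labelled standards — spiked at one fixed level, not the
#'   calibrant series — are not scanned).
#' @return Tibble with `compound`, `level` (ng/mL) and `sn`, sorted by
#'   compound then level.
#' @export
sn_series <- function(peaks, manifest, compounds = NULL) {
  cal <- manifest[manifest$sample_type == "calibrant", , drop = FALSE]
  quant <- peaks[peaks$transition == "quant" &
                   peaks$sample_id %in% cal$sample_id, , drop = FALSE]
  if (!is.null(compounds)) {
    quant <- quant[quant$compound %in% compounds, , drop = FALSE]
  }
  quant <- quant %>%
    left_join(cal[, c("sample_id", "nominal_ngml")], by = "sample_id")
  no_noise <- unique(quant$compound[is.na(quant$noise_sd)])
  if (length(no_noise) > 0) {
    warn(paste0("no noise_sd for ", paste(no_noise, collapse = ", "),
                "; excluded from S/N series"))
    quant <- quant[!is.na(quant$noise_sd), , drop = FALSE]
  }
  if (any(quant$noise_sd == 0)) abort("noise_sd must be > 0 (division guard)")
  quant %>%
    mutate(sn = .data$height / .data$noise_sd) %>%
    group_by(.data$compound, level = .data$nominal_ngml) %>%
    summarise(sn = mean(.data$sn), .groups = "drop") %>%
    arrange(.data$compound, .data$level)
}

lowest_monotone_level <- function(level, sn, threshold) {
  ord <- order(level)
  level <- level[ord]; sn <- sn[ord]
  below <- which(sn < threshold)
  if (length(below) == 0) return(level[1])
  if (max(below) == length(level)) return(NA_real_)
  level[max(below) + 1]
}

#' Per-run LOD and LOQ by the monotone-suffix threshold scan
#'
#' The run LOD is the lowest calibrant level whose S/N is at least 3 such
#' that every higher level also reaches 3; the LOQ is defined the same way
#' at threshold 10. This deterministic scan replaces the manual visual
#' determination of routine practice: an isolated low level that crosses a
#' threshold while a higher level fails it does not count (non-monotone
#' series resolve to the start of the uninterrupted suffix). Levels that
#' never reach a threshold yield `NA` ("not determined this run"); the LOQ
#' is never below the LOD.
#'
#' @param sn_tbl output of [sn_series()] (one or many compounds).
#' @param lod_sn,loq_sn S/N thresholds (defaults 3 and 10).
#' @return Tibble with `compound`, `lod_run`, `loq_run` (ng/mL).
#' @export
run_lod_loq <- function(sn_tbl, lod_sn = 3, loq_sn = 10) {
  sn_tbl %>%
    group_by(.data$compound) %>%
    summarise(
      lod_run = lowest_monotone_level(.data$level, .data$sn, lod_sn),
      loq_run = lowest_monotone_level(.data$level, .data$sn, loq_sn),
      .groups = "drop")
}

#' Conservative reporting rule against a five-run reference
#'
#' Once a compound has five determined run values, their arithmetic mean
#' becomes a frozen reference. A run value below the reference is replaced
#' by the reference (consistency); a run value above it is kept
#' (conservatism). Both branches reduce to `max(run, reference)`. Before
#' the reference exists, the run value is reported unchanged.
#'
#' @param run_value per-run LOD or LOQ determination(s), ng/mL.
#' @param reference the five-run reference average, or `NA` if not yet
#'   established.
#' @return Reported value(s), never below an established reference.
#' @export
apply_reference_rule <- function(run_value, reference) {
  ifelse(is.na(reference), run_value, pmax(run_value, reference))
}

#' @rdname read_lodloq_state
#' @export
new_lodloq_state <- function() {
  structure(list(), class = "wbe_lodloq_state")
}

#' Persistent LOD/LOQ reference state
#'
#' The reference average is built from the first five determined runs per
#' compound and frozen thereafter. State is stored as human-readable JSON
#' keyed by compound, each entry holding the accumulated `lod` and `loq`
#' determinations. Non-detects (runs where no level reached a threshold)
#' never contribute.
#'
#' @param path JSON state file; a missing file yields an empty state.
#' @return A `wbe_lodloq_state` list.
#' @export
read_lodloq_state <- function(path) {
  if (!file.exists(path)) return(new_lodloq_state())
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  state <- lapply(raw, function(x) {
    list(lod = as.numeric(x$lod), loq = as.numeric(x$loq))
  })
  structure(state, class = "wbe_lodloq_state")
}

#' @rdname read_lodloq_state
#' @param state a `wbe_lodloq_state`.
#' @export
write_lodloq_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

reference_of <- function(values, n_ref = 5) {
  if (length(values) >= n_ref) mean(values[seq_len(n_ref)]) else NA_real_
}

#' Evaluate run sensitivity and update the reference state
#'
#' Computes per-run LOD/LOQ from the run's calibrant S/N series, reports
#' them through [apply_reference_rule()] against the current references,
#' and appends determined values to the state (only until five exist; the
#' reference is frozen afterwards).
#'
#' @param peaks,manifest the run's peak table and manifest.
#' @param state a `wbe_lodloq_state` (default: empty).
#' @param run_id label recorded on the output.
#' @param n_ref number of determinations that define the reference.
#' @param compounds optional analyte restriction passed to [sn_series()].
#' @return List with `records` (tibble: compound, run_id, lod_run, loq_run,
#'   reference_lod, reference_loq, lod_reported, loq_reported) and the
#'   updated `state`.
#' @export
sensitivity_evaluate <- function(peaks, manifest, state = new_lodloq_state(),
                                 run_id = "run1", n_ref = 5,
                                 compounds = NULL) {
  runs <- run_lod_loq(sn_series(peaks, manifest, compounds = compounds))
  records <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    cmp <- runs$compound[i]
    entry <- state[[cmp]] %||% list(lod = numeric(0), loq = numeric(0))
    ref_lod <- reference_of(entry$lod, n_ref)
    ref_loq <- reference_of(entry$loq, n_ref)
    lod_run <- runs$lod_run[i]; loq_run <- runs$loq_run[i]
    records[[i]] <- tibble(
      compound = cmp, run_id = run_id,
      lod_run = lod_run, loq_run = loq_run,
      reference_lod = ref_lod, reference_loq = ref_loq,
      lod_reported = apply_reference_rule(lod_run, ref_lod),
      loq_reported = apply_reference_rule(loq_run, ref_loq))
    if (!is.na(lod_run) && length(entry$lod) < n_ref) {
      entry$lod <- c(entry$lod, lod_run)
    }
    if (!is.na(loq_run) && length(entry$loq) < n_ref) {
      entry$loq <- c(entry$loq, loq_run)
    }
    state[[cmp]] <- entry
  }
  list(records = bind_rows(records), state = state)
}

#' Censor a concentration against detection and quantitation limits
#'
#' Half-open convention: `conc < lod` is `below_lod`;
#' `lod <= conc < loq` is `between_lod_loq`; `conc >= loq` is `quantified`.
#' Negative concentrations (inverse predictions below the intercept) are
#' `below_lod`. Vectorized; `NA` limits leave the value `quantified` only
#' if non-negative and both limits are `NA`.
#'
#' @param conc concentration(s), any unit shared with the limits.
#' @param lod,loq detection/quantitation limits (lod <= loq).
#' @return Character vector of statuses.
#' @export
censor_status <- function(conc, lod, loq) {
  if (any(!is.na(lod) & !is.na(loq) & lod > loq)) {
    abort("lod must not exceed loq")
  }
  status <- rep("quantified", length(conc))
  below <- conc < 0 | (!is.na(lod) & conc < lod)
  between <- !below & !is.na(loq) & conc < loq
  status[between] <- "between_lod_loq"
  status[below] <- "below_lod"
  status
}
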