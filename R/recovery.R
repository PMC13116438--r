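#' Extraction efficiency from spike-before/spike-after replicates
#'
#' Recovery is 100 x mean(areas spiked before extraction) / mean(areas
#' spiked after extraction): the fraction of analyte surviving the
#' solid-phase extraction, as a percentage. Values above 100% are reported
#' as-is — they signal matrix enhancement, not an error. Precision is, by
#' default, the RSD of the before-spike (whole-method) replicates; the RSD
#' of replicate-wise before/after ratios is selectable (`rsd_on =
#' "ratio"`, replicates paired by position). A non-positive after-spike
#' mean leaves both values missing with a reason.
#'
#' @param before peak areas of replicates spiked before extraction.
#' @param after peak areas of replicates spiked after extraction.
#' @param rsd_on `"before"` or `"ratio"` (see above).
#' @return One-row tibble: `recovery_pct`, `rsd_pct`, `n_before`,
#'   `n_after`, `reason` (`NA` unless the result is missing).
#' @export
extraction_efficiency <- function(before, after,
                                  rsd_on = c("before", "ratio")) {
  rsd_on <- match.arg(rsd_on)
  before <- before[!is.na(before)]
  after <- after[!is.na(after)]
  if (length(before) == 0 || length(after) == 0) {
    return(tibble(recovery_pct = NA_real_, rsd_pct = NA_real_,
                  n_before = length(before), n_after = length(after),
                  reason = "empty replicate arm"))
  }
  if (mean(after) <= 0) {
    return(tibble(recovery_pct = NA_real_, rsd_pct = NA_real_,
                  n_before = length(before), n_after = length(after),
                  reason = "after-spike mean not positive"))
  }
  recovery <- 100 * mean(before) / mean(after)
  rsd <- if (rsd_on == "before") {
    if (length(before) >= 2) 100 * sd(before) / mean(before) else NA_real_
  } else {
    if (length(before) == length(after) && length(before) >= 2) {
      r <- before / after
      100 * sd(r) / mean(r)
    } else NA_real_
  }
  tibble(recovery_pct = recovery, rsd_pct = rsd,
         n_before = length(before), n_after = length(after),
         reason = NA_character_)
}

#' Group recovery-experiment peak areas from a manifest
#'
#' Collects quantifier areas of `spike_before` and `spike_after` samples,
#' paired through `replicate_group` and split by `sorbent`. Groups with
#' only one arm are excluded with a warning naming them.
#'
#' @param peaks peak tibble.
#' @param manifest manifest containing the recovery samples.
#' @return Tibble with `compound`, `sorbent`, `arm` (`before`/`after`),
#'   `replicate_group`, `sample_id`, `area`.
#' @export
recovery_experiment_from_manifest <- function(peaks, manifest) {
  rec <- manifest[manifest$sample_type %in%
                    c("spike_before", "spike_after"), , drop = FALSE]
  rec$sorbent[is.na(rec$sorbent)] <- "unspecified"
  arms <- rec %>%
    group_by(.data$sorbent, .data$replicate_group) %>%
    summarise(n_arms = length(unique(.data$sample_type)), .groups = "drop")
  incomplete <- arms[arms$n_arms < 2, , drop = FALSE]
  if (nrow(incomplete) > 0) {
    warn(paste0("recovery group(s) with a single arm excluded: ",
                paste(incomplete$replicate_group, collapse = ", ")))
    rec <- rec %>%
      dplyr::anti_join(incomplete[, c("sorbent", "replicate_group")],
                       by = c("sorbent", "replicate_group"))
  }
  quant <- peaks[peaks$transition == "quant" &
                   peaks$sample_id %in% rec$sample_id, , drop = FALSE]
  quant %>%
    left_join(rec[, c("sample_id", "sample_type", "sorbent",
                      "replicate_group")], by = "sample_id") %>%
    mutate(arm = ifelse(.data$sample_type == "spike_before",
                        "before", "after")) %>%
    select("compound", "sorbent", "arm", "replicate_group", "sample_id",
           "area")
}

#' Per-compound, per-sorbent recovery table
#'
#' Runs [extraction_efficiency()] on every (compound, sorbent) group of a
#' recovery experiment. Labelled internal standards present in the peak
#' table get rows like any other species.
#'
#' @inheritParams recovery_experiment_from_manifest
#' @param rsd_on passed to [extraction_efficiency()].
#' @return Tibble with `compound`, `sorbent`, `recovery_pct`, `rsd_pct`,
#'   `n_before`, `n_after`, `reason`.
#' @export
recovery_table <- function(peaks, manifest, rsd_on = c("before", "ratio")) {
  rsd_on <- match.arg(rsd_on)
  grouped <- recovery_experiment_from_manifest(peaks, manifest)
  out <- list()
  for (key in unique(paste(grouped$compound, grouped$sorbent, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- grouped[grouped$compound == parts[1] &
                     grouped$sorbent == parts[2], , drop = FALSE]
    eff <- extraction_efficiency(sub$area[sub$arm == "before"],
                                 sub$area[sub$arm == "after"],
                                 rsd_on = rsd_on)
    out[[key]] <- mutate(eff, compound = parts[1], sorbent = parts[2],
                         .before = 1)
  }
  bind_rows(out) %>% arrange(.data$sorbent, .data$compound)
}

#' Sorbent comparison summary
#'
#' Mean recovery and mean RSD per sorbent across compounds, excluding
#' missing (N/A) entries from that sorbent's mean only — a compound
#' unrecovered on one sorbent still counts on the other.
#'
#' @param rec_tbl output of [recovery_table()].
#' @return Tibble with `sorbent`, `n_compounds`, `mean_recovery_pct`,
#'   `mean_rsd_pct`.
#' @export
compare_sorbents <- function(rec_tbl) {
  rec_tbl %>%
    filter(!is.na(.data$recovery_pct)) %>%
    group_by(.data$sorbent) %>%
    summarise(
      n_compounds = n(),
      mean_recovery_pct = mean(.data$recovery_pct),
      mean_rsd_pct = mean(.data$rsd_pct, na.rm = TRUE),
      .groups = "drop")
}
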