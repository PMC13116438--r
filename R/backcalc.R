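#' Population-normalized excretion rate
#'
#' Converts a wastewater concentration to the daily biomarker mass load
#' through the treatment facility, normalized per 1000 inhabitants served:
#' `rate = conc_ngl * flow_l_per_day * 1e-6 / (population / 1000)`
#' (the 1e-6 converts ng to mg). Units: mg/day per 1000 inhabitants.
#'
#' @param conc_ngl wastewater concentration, ng/L (>= 0).
#' @param flow_l_per_day facility influent flow, L/day (> 0).
#' @param population population served by the catchment (> 0).
#' @return Excretion rate(s), mg/day per 1000 inhabitants.
#' @export
excretion_rate <- function(conc_ngl, flow_l_per_day, population) {
  if (any(is.na(flow_l_per_day) | flow_l_per_day <= 0)) {
    abort("flow_l_per_day must be > 0")
  }
  if (any(is.na(population) | population <= 0)) {
    abort("population must be > 0")
  }
  if (any(!is.na(conc_ngl) & conc_ngl < 0)) abort("conc_ngl must be >= 0")
  conc_ngl * flow_l_per_day * 1e-6 / (population / 1000)
}

#' Consumption rate from an excretion rate
#'
#' Divides the excretion rate by the fraction of the consumed dose excreted
#' in urine as the measured biomarker; when the biomarker is a metabolite
#' rather than the parent drug, further multiplies by the ratio of the
#' parent's molecular weight to the metabolite's to account for
#' biotransformation. A missing excretion fraction yields `NA` (consumption
#' cannot be estimated), not an error.
#'
#' @param excretion excretion rate(s), mg/day per 1000 inhabitants.
#' @param excretion_fraction fraction of dose excreted as the biomarker,
#'   in (0, 1].
#' @param mw_parent,mw_metabolite molecular weights, g/mol (required when
#'   `measured_is_metabolite`).
#' @param measured_is_metabolite whether the biomarker is a metabolite of
#'   the consumed parent drug.
#' @return Consumption rate(s), mg/day per 1000 inhabitants, `NA` where the
#'   excretion fraction is unknown.
#' @export
consumption_rate <- function(excretion, excretion_fraction,
                             mw_parent = NA_real_, mw_metabolite = NA_real_,
                             measured_is_metabolite = FALSE) {
  if (any(!is.na(excretion_fraction) &
            (excretion_fraction <= 0 | excretion_fraction > 1))) {
    abort("excretion_fraction must be in (0, 1]")
  }
  mw_ratio <- ifelse(measured_is_metabolite, mw_parent / mw_metabolite, 1)
  out <- excretion / excretion_fraction * mw_ratio
  out[is.na(excretion_fraction)] <- NA_real_
  out
}

#' Excretion and consumption rates for a quantified dataset
#'
#' Joins each field-sample measurement to its site's flow and population
#' (per-date flow where the sites table carries `measured_on`, else the
#' site constant), substitutes censored concentrations under the configured
#' policy, and back-calculates both rates. Metabolite-derived consumption
#' is attributed to the parent compound name. Missing site joins are an
#' error listing the offending sample ids.
#'
#' @param measurements tibble from [quantify_batch()] (field samples).
#' @param manifest the manifest (source of `site_id`/`collected_on`).
#' @param sites tibble from [read_sites()].
#' @param panel a `wbe_panel` supplying pharmacokinetic constants.
#' @param substitution censoring substitution policy
#'   (see [substitute_censored()]).
#' @return Tibble with `site_id`, `collected_on`, `compound`,
#'   `parent_compound`, `excretion_mg_day_1000`, `consumption_mg_day_1000`,
#'   `status`.
#' @export
rates_for_dataset <- function(measurements, manifest, sites, panel,
                              substitution = c("half_lod", "zero",
                                               "lod_sqrt2", "exclude")) {
  substitution <- match.arg(substitution)
  field_ids <- manifest$sample_id[manifest$sample_type == "field"]
  m <- measurements[measurements$sample_id %in% field_ids, , drop = FALSE] %>%
    left_join(manifest[, c("sample_id", "site_id", "collected_on")],
              by = "sample_id")
  if ("measured_on" %in% names(sites) && any(!is.na(sites$measured_on))) {
    m <- m %>%
      left_join(sites, by = c(site_id = "site_id",
                              collected_on = "measured_on"))
    const <- sites[is.na(sites$measured_on), , drop = FALSE]
    if (nrow(const) > 0) {
      backfill <- is.na(m$population)
      if (any(backfill)) {
        fill <- m[backfill, c("sample_id", "site_id")] %>%
          left_join(const[, c("site_id", "population", "flow_l_per_day")],
                    by = "site_id")
        m$population[backfill] <- fill$population
        m$flow_l_per_day[backfill] <- fill$flow_l_per_day
      }
    }
  } else {
    m <- m %>%
      left_join(sites[, c("site_id", "population", "flow_l_per_day")],
                by = "site_id")
  }
  unjoined <- m$sample_id[is.na(m$population) | is.na(m$flow_l_per_day)]
  if (length(unjoined) > 0) {
    abort(paste0("no site flow/population for sample(s): ",
                 paste(unique(unjoined), collapse = ", ")))
  }
  conc <- substitute_censored(m$sample_conc_ngl, m$status, m$lod_ngl,
                              policy = if (substitution == "exclude")
                                "zero" else substitution)
  if (substitution == "exclude") conc[m$status == "below_lod"] <- NA_real_
  conc[is.na(conc) & m$status != "not_quantifiable" &
         m$status != "below_lod"] <- NA_real_
  pk <- pk_table(panel)
  m <- m %>% left_join(pk, by = "compound")
  usable <- !is.na(conc)
  exc <- rep(NA_real_, nrow(m))
  exc[usable] <- excretion_rate(conc[usable], m$flow_l_per_day[usable],
                                m$population[usable])
  cons <- rep(NA_real_, nrow(m))
  cons[usable] <- consumption_rate(
    exc[usable], m$excretion_fraction[usable],
    m$mw_parent[usable], m$mw_metabolite[usable],
    m$measured_is_metabolite[usable])
  tibble(
    site_id = m$site_id,
    collected_on = m$collected_on,
    compound = m$compound,
    parent_compound = m$parent_compound,
    excretion_mg_day_1000 = exc,
    consumption_mg_day_1000 = cons,
    status = m$status)
}

#' Dataset-mean rates per compound
#'
#' Means over all site-weeks, computed on the substituted values already in
#' the rate table; compounds whose records are all censored are flagged.
#'
#' @param rates output of [rates_for_dataset()].
#' @return Tibble with per-compound means and censoring counts.
#' @export
rate_means <- function(rates) {
  rates %>%
    group_by(compound = .data$compound,
             parent_compound = .data$parent_compound) %>%
    summarise(
      mean_excretion_mg_day_1000 = mean(.data$excretion_mg_day_1000,
                                        na.rm = TRUE),
      mean_consumption_mg_day_1000 = mean(.data$consumption_mg_day_1000,
                                          na.rm = TRUE),
      n = n(),
      n_censored = sum(.data$status != "quantified"),
      all_censored = all(.data$status != "quantified"),
      .groups = "drop")
}
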