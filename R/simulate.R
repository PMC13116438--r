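#' Configuration for the synthetic-batch generator
#'
#' Defines the generating model for a complete analytical batch: a
#' calibrant series (default: the 22-level, 0.001-200 ng/mL design), a
#' method blank, spiked QC replicates, and a grid of field samples over
#' sites and weekly collections. Areas follow the detector model
#' `native area = extract conc x area_per_ng x suppression x LN(1, cv)`
#' and `IS area = is_area_nominal x suppression x LN(1, cv)`, where
#' `LN(1, cv)` is mean-one lognormal multiplicative noise and
#' `suppression` is a per-sample matrix factor applied equally to native
#' and IS — the common factor cancels in the response ratio, which is why
#' isotope dilution works. An optional `differential_suppression` knob
#' multiplies only the native by an extra per-sample factor to break the
#' cancellation for stress tests. Peak heights are proportional to areas
#' and a constant baseline `noise_floor_sd` fills the noise column.
#'
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @param compounds character vector of native analytes to simulate
#'   (default: three representative panel members).
#' @param panel the `wbe_panel` supplying IS assignments.
#' @param calibration_levels calibrant concentrations, ng/mL.
#' @param true_field_conc named vector of true wastewater concentrations
#'   (ng/L) per compound, or `NULL` to draw per-site-week values from a
#'   lognormal with `field_median_ngl` and `field_gcv`.
#' @param field_median_ngl,field_gcv median (ng/L) and geometric CV of the
#'   field-truth lognormal when `true_field_conc` is `NULL`.
#' @param area_per_ng detector response, area units per (ng/mL).
#' @param is_area_nominal nominal internal-standard area.
#' @param noise_cv multiplicative lognormal CV on each peak area.
#' @param suppression_range per-sample matrix factor range, within
#'   (0, 1.5].
#' @param differential_suppression extra CV of a native-only suppression
#'   factor (0 disables; > 0 breaks isotope-dilution cancellation).
#' @param noise_floor_sd baseline noise standard deviation (height units).
#' @param height_per_area peak height per unit area.
#' @param qc_nominal_ngml spiked-QC nominal concentration, ng/mL.
#' @param n_sites,n_weeks field-sample grid dimensions.
#' @param replicates QC replicate count.
#' @param mass_g,density_g_per_ml,extract_volume_ml sample-prep constants.
#' @return A validated `wbe_sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       compounds = c("amphetamine", "methamphetamine",
                                     "benzoylecgonine"),
                       panel = default_panel(),
                       calibration_levels = default_calibration_levels(),
                       true_field_conc = NULL,
                       field_median_ngl = 500, field_gcv = 1.0,
                       area_per_ng = 2e4, is_area_nominal = 1e5,
                       noise_cv = 0.05,
                       suppression_range = c(0.6, 1.2),
                       differential_suppression = 0,
                       noise_floor_sd = 10, height_per_area = 0.1,
                       qc_nominal_ngml = 50,
                       n_sites = 17, n_weeks = 35, replicates = 3,
                       mass_g = 100, density_g_per_ml = 1.0,
                       extract_volume_ml = 0.5) {
  stopifnot(length(compounds) >= 1,
            all(compounds %in% panel$natives$name),
            all(calibration_levels > 0), length(calibration_levels) >= 3,
            area_per_ng > 0, is_area_nominal > 0, noise_cv >= 0,
            suppression_range[1] > 0, suppression_range[2] <= 1.5,
            noise_floor_sd > 0, height_per_area > 0,
            qc_nominal_ngml > 0, n_sites >= 1, n_weeks >= 1,
            replicates >= 2, mass_g > 0, density_g_per_ml > 0,
            extract_volume_ml > 0)
  structure(list(
    seed = seed, compounds = compounds, panel = panel,
    calibration_levels = sort(calibration_levels),
    true_field_conc = true_field_conc,
    field_median_ngl = field_median_ngl, field_gcv = field_gcv,
    area_per_ng = area_per_ng, is_area_nominal = is_area_nominal,
    noise_cv = noise_cv, suppression_range = suppression_range,
    differential_suppression = differential_suppression,
    noise_floor_sd = noise_floor_sd, height_per_area = height_per_area,
    qc_nominal_ngml = qc_nominal_ngml,
    n_sites = n_sites, n_weeks = n_weeks, replicates = replicates,
    mass_g = mass_g, density_g_per_ml = density_g_per_ml,
    extract_volume_ml = extract_volume_ml), class = "wbe_sim_config")
}

sim_peak_rows <- function(sample_id, compound, extract_conc, config,
                          suppression) {
  native_noise <- rlnorm_cv(1, config$noise_cv)
  diff_supp <- if (config$differential_suppression > 0) {
    rlnorm_cv(1, config$differential_suppression)
  } else 1
  is_noise <- rlnorm_cv(1, config$noise_cv)
  nat_area <- extract_conc * config$area_per_ng * suppression *
    diff_supp * native_noise
  is_area <- config$is_area_nominal * suppression * is_noise
  is_name <- config$panel$natives$is_name[
    config$panel$natives$name == compound]
  tibble(
    sample_id = sample_id,
    compound = c(compound, compound, is_name),
    transition = c("quant", "confirm", "quant"),
    area = c(nat_area, nat_area * 0.35, is_area),
    height = c(nat_area, nat_area * 0.35, is_area) *
      config$height_per_area,
    noise_sd = config$noise_floor_sd)
}

#' Generate one complete synthetic batch
#'
#' Emits the four artifacts the pipeline consumes — a long peak table, a
#' sample manifest, a sites table — plus a truth table recording every
#' generating value (true extract and wastewater concentrations per
#' sample-compound) for assertions. The batch comprises one calibrant per
#' level, one method blank, `replicates` spiked QCs at
#' `qc_nominal_ngml`, and `n_sites x n_weeks` field samples.
#'
#' @param config a `wbe_sim_config`.
#' @return List with `peaks`, `manifest`, `sites`, `truth` tibbles.
#' @export
simulate_batch <- function(config) {
  stopifnot(inherits(config, "wbe_sim_config"))
  with_seed(config$seed, {
    factor <- concentration_factor(config$mass_g, config$density_g_per_ml,
                                   config$extract_volume_ml)
    manifest <- list(); truths <- list(); peaks <- list()
    add_sample <- function(meta, concs) {
      manifest[[length(manifest) + 1]] <<- meta
      supp <- stats::runif(1, config$suppression_range[1],
                           config$suppression_range[2])
      for (j in seq_along(config$compounds)) {
        cmp <- config$compounds[j]
        peaks[[length(peaks) + 1]] <<-
          sim_peak_rows(meta$sample_id, cmp, concs[j], config, supp)
      }
      truths[[length(truths) + 1]] <<- tibble(
        sample_id = meta$sample_id, compound = config$compounds,
        true_extract_ngml = concs, suppression = supp)
    }
    for (i in seq_along(config$calibration_levels)) {
      lev <- config$calibration_levels[i]
      add_sample(tibble(sample_id = sprintf("cal%02d", i),
                        sample_type = "calibrant", nominal_ngml = lev,
                        mass_g = NA_real_, density_g_per_ml = 1,
                        site_id = NA_character_,
                        collected_on = as.Date(NA),
                        replicate_group = NA_character_,
                        sorbent = NA_character_),
                 rep(lev, length(config$compounds)))
    }
    add_sample(tibble(sample_id = "blank1", sample_type = "blank",
                      nominal_ngml = NA_real_, mass_g = NA_real_,
                      density_g_per_ml = 1, site_id = NA_character_,
                      collected_on = as.Date(NA),
                      replicate_group = NA_character_,
                      sorbent = NA_character_),
               rep(0, length(config$compounds)))
    for (r in seq_len(config$replicates)) {
      add_sample(tibble(sample_id = paste0("qc", r),
                        sample_type = "qc_spiked",
                        nominal_ngml = config$qc_nominal_ngml,
                        mass_g = NA_real_, density_g_per_ml = 1,
                        site_id = NA_character_,
                        collected_on = as.Date(NA),
                        replicate_group = NA_character_,
                        sorbent = NA_character_),
                 rep(config$qc_nominal_ngml, length(config$compounds)))
    }
    sites <- tibble(
      site_id = sprintf("site%02d", seq_len(config$n_sites)),
      population = round(stats::runif(config$n_sites, 5e4, 5e5)),
      flow_l_per_day = stats::runif(config$n_sites, 5e6, 5e7),
      measured_on = as.Date(NA))
    start <- as.Date("2025-01-06")
    truth_field <- list()
    for (s in seq_len(config$n_sites)) {
      for (w in seq_len(config$n_weeks)) {
        sid <- sprintf("f_%02d_%02d", s, w)
        ngl <- if (!is.null(config$true_field_conc)) {
          unname(config$true_field_conc[config$compounds])
        } else {
          sdlog <- sqrt(log(1 + config$field_gcv^2))
          rlnorm(length(config$compounds),
                 meanlog = log(config$field_median_ngl), sdlog = sdlog)
        }
        add_sample(tibble(sample_id = sid, sample_type = "field",
                          nominal_ngml = NA_real_, mass_g = config$mass_g,
                          density_g_per_ml = config$density_g_per_ml,
                          site_id = sites$site_id[s],
                          collected_on = start + 7 * (w - 1),
                          replicate_group = NA_character_,
                          sorbent = NA_character_),
                   ngl / factor)
        truth_field[[sid]] <- tibble(
          sample_id = sid, compound = config$compounds,
          true_sample_ngl = ngl)
      }
    }
    truth <- bind_rows(truths) %>%
      left_join(bind_rows(truth_field), by = c("sample_id", "compound"))
    list(peaks = validate_peaks(bind_rows(peaks)),
         manifest = validate_manifest(bind_rows(manifest)),
         sites = validate_sites(sites),
         truth = truth)
  })
}

#' Synthetic isotope-dilution calibration series
#'
#' Response ratios with mean-one lognormal multiplicative noise around the
#' generating line: `ratio = (intercept + slope x level) x LN(1, cv)`. This
#' is the series [fit_calibration()] consumes, at the precision the
#' isotope-dilution ratio actually carries.
#'
#' @param levels calibrant concentrations, ng/mL.
#' @param slope,intercept generating line (ratio per ng/mL; ratio).
#' @param cv multiplicative noise CV of the response ratio.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return Tibble with `nominal_ngml` and `ratio`.
#' @export
simulate_calibration_ratios <- function(levels, slope = 1, intercept = 0,
                                        cv = 0.05, seed = NULL) {
  with_seed(seed, tibble(
    nominal_ngml = levels,
    ratio = (intercept + slope * levels) * rlnorm_cv(length(levels), cv)))
}

#' Synthetic spike-before/spike-after recovery replicates
#'
#' Before-spike areas are `after_scale x truth x LN(1, cv)`; after-spike
#' areas are `after_scale x LN(1, cv)`; `truth` is the generating
#' extraction efficiency as a fraction (may exceed 1 for matrix
#' enhancement).
#'
#' @param truth true before/after efficiency (fraction, e.g. 0.85).
#' @param cv multiplicative noise CV per replicate.
#' @param n replicates per arm (default 3).
#' @param after_scale detector scale of the after-spike areas.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return List with numeric vectors `before` and `after`.
#' @export
simulate_recovery <- function(truth, cv = 0.10, n = 3, after_scale = 1e5,
                              seed = NULL) {
  stopifnot(truth >= 0, truth <= 2.5)
  with_seed(seed, list(
    before = after_scale * truth * rlnorm_cv(n, cv),
    after = after_scale * rlnorm_cv(n, cv)))
}

#' Synthetic dilution series for LOD/LOQ studies
#'
#' Peak height follows a linear response plus additive Gaussian baseline
#' noise: `height = max(slope x level + N(0, noise_sd), 0)`; the `noise_sd`
#' column carries the generating baseline SD so S/N is
#' `height / noise_sd`.
#'
#' @param levels calibrant concentrations, ng/mL.
#' @param slope height units per (ng/mL).
#' @param noise_sd baseline noise standard deviation.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return Tibble with `level`, `height`, `noise_sd`, `sn`.
#' @export
simulate_sn_series <- function(levels, slope = 300, noise_sd = 10,
                               seed = NULL) {
  stopifnot(noise_sd > 0)
  with_seed(seed, {
    height <- pmax(slope * levels + rnorm(length(levels), 0, noise_sd), 0)
    tibble(level = levels, height = height, noise_sd = noise_sd,
           sn = height / noise_sd)
  })
}
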