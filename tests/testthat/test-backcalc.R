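test_that("excretion rate follows the flow-population unit chain", {
  # 1000 ng/L * 1e7 L/day = 1e10 ng/day = 1e4 mg/day over 100k persons
  expect_equal(excretion_rate(1000, 1e7, 1e5), 100)
  expect_equal(excretion_rate(0, 1e7, 1e5), 0)
  expect_equal(excretion_rate(1000, 1e7, 2e5), 50)   # doubling population
  expect_error(excretion_rate(10, 0, 1e5), "flow")
  expect_error(excretion_rate(10, 1e7, -1), "population")
  expect_error(excretion_rate(-10, 1e7, 1e5), "conc")
})

test_that("consumption applies the excretion fraction and MW correction", {
  expect_equal(consumption_rate(100, 0.5), 200)
  expect_equal(consumption_rate(100, 0.5, mw_parent = 360,
                                mw_metabolite = 300,
                                measured_is_metabolite = TRUE), 240)
  expect_equal(consumption_rate(100, 1.0), 100)
  expect_true(is.na(consumption_rate(100, NA)))
  expect_error(consumption_rate(100, 1.7), "excretion_fraction")
})

test_that("consumption dominates excretion when fraction <= 1 and MW ratio >= 1", {
  set.seed(41)
  for (i in 1:30) {
    e <- stats::runif(1, 0, 500)
    f <- stats::runif(1, 0.05, 1)
    mwp <- stats::runif(1, 200, 500)
    mwm <- stats::runif(1, 100, mwp)
    expect_gte(consumption_rate(e, f, mwp, mwm, TRUE), e)
    expect_gte(consumption_rate(e, f), e)
  }
})

test_that("rates are exactly linear in concentration and flow", {
  c0 <- 321.7; f0 <- 1.3e7; p0 <- 2.2e5
  base <- excretion_rate(c0, f0, p0)
  for (k in c(0.1, 2, 7.5)) {
    expect_equal(excretion_rate(k * c0, f0, p0), k * base)
    expect_equal(excretion_rate(c0, k * f0, p0), k * base)
    expect_equal(consumption_rate(k * base, 0.4), k * base / 0.4)
  }
})

make_rates_inputs <- function(n_sites = 2, n_weeks = 3) {
  cfg <- tiny_config(seed = 43, cv = 0, n_sites = n_sites,
                     n_weeks = n_weeks)
  b <- simulate_batch(cfg)
  fits <- fit_calibrations(response_ratios(b$peaks, b$manifest, cfg$panel))
  m <- quantify_batch(b$peaks, b$manifest, fits, panel = cfg$panel)
  list(cfg = cfg, b = b, m = m)
}

test_that("dataset rates join sites and attribute metabolites to parents", {
  x <- make_rates_inputs()
  rates <- rates_for_dataset(x$m, x$b$manifest, x$b$sites, x$cfg$panel)
  field_n <- sum(x$b$manifest$sample_type == "field")
  expect_equal(nrow(rates), field_n * 2)   # n_sites*n_weeks per compound
  expect_true(all(rates$parent_compound[rates$compound == "drugA"] ==
                    "drugA"))
  # noise-free chain: excretion recomputes exactly from truth
  truth <- x$b$truth[!is.na(x$b$truth$true_sample_ngl), ]
  one <- rates[rates$compound == "drugA", ][1, ]
  site <- x$b$sites[x$b$sites$site_id == one$site_id, ]
  tr <- truth$true_sample_ngl[truth$compound == "drugA"][1]
  expect_equal(one$excretion_mg_day_1000,
               excretion_rate(tr, site$flow_l_per_day, site$population),
               tolerance = 1e-9)
  # missing site is an error naming samples
  expect_error(
    rates_for_dataset(x$m, x$b$manifest, x$b$sites[-1, ], x$cfg$panel),
    "f_01")
})

test_that("metabolite consumption uses the parent molecular weight", {
  panel <- tiny_panel()
  manifest <- validate_manifest(tibble::tibble(
    sample_id = "f1", sample_type = "field", nominal_ngml = NA_real_,
    mass_g = 100, density_g_per_ml = 1, site_id = "s1",
    collected_on = as.Date("2025-02-03"),
    replicate_group = NA_character_, sorbent = NA_character_))
  sites <- validate_sites(tibble::tibble(
    site_id = "s1", population = 1e5, flow_l_per_day = 1e7,
    measured_on = as.Date(NA)))
  m <- tibble::tibble(
    batch_id = "b1", sample_id = "f1", compound = "metA",
    extract_conc_ngml = 200, sample_conc_ngl = 1000,
    status = "quantified", lod_ngl = 1, loq_ngl = 5, qc_pass = TRUE)
  rates <- rates_for_dataset(m, manifest, sites, panel)
  expect_equal(rates$parent_compound, "drugA")
  # excretion 100; fraction 0.25; MW ratio 150/120
  expect_equal(rates$excretion_mg_day_1000, 100)
  expect_equal(rates$consumption_mg_day_1000, 100 / 0.25 * 150 / 120)
})

test_that("censored field records follow the substitution policy in rates", {
  panel <- tiny_panel()
  manifest <- validate_manifest(tibble::tibble(
    sample_id = "f1", sample_type = "field", nominal_ngml = NA_real_,
    mass_g = 100, density_g_per_ml = 1, site_id = "s1",
    collected_on = as.Date("2025-02-03"),
    replicate_group = NA_character_, sorbent = NA_character_))
  sites <- validate_sites(tibble::tibble(
    site_id = "s1", population = 1e5, flow_l_per_day = 1e7,
    measured_on = as.Date(NA)))
  m <- tibble::tibble(
    batch_id = "b1", sample_id = "f1", compound = "drugA",
    extract_conc_ngml = -0.1, sample_conc_ngl = 0,
    status = "below_lod", lod_ngl = 10, loq_ngl = 50, qc_pass = TRUE)
  half <- rates_for_dataset(m, manifest, sites, panel, "half_lod")
  expect_equal(half$excretion_mg_day_1000, excretion_rate(5, 1e7, 1e5))
  expect_equal(half$status, "below_lod")
  zero <- rates_for_dataset(m, manifest, sites, panel, "zero")
  expect_equal(zero$excretion_mg_day_1000, 0)
  # all-censored compounds are flagged in the dataset means
  means <- rate_means(half)
  expect_true(means$all_censored)
})
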