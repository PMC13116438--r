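test_that("concentration factor follows the gravimetric unit chain", {
  # 100 g at density 1.0 is 0.1 L; 0.5 mL extract concentrates 200x -> 5
  expect_equal(concentration_factor(100, 1.0, 0.5), 5)
  expect_equal(10 * concentration_factor(100, 1.0, 0.5), 50)
  # density-corrected mass gives the same volume
  expect_equal(concentration_factor(102, 1.02, 0.5),
               concentration_factor(100, 1.00, 0.5))
  expect_error(concentration_factor(0, 1, 0.5), "mass_g")
  expect_error(concentration_factor(100, 0, 0.5), "density")
  expect_error(concentration_factor(100, 1, 0), "extract_volume")
})

test_that("unit coherence: mass and extract volume scale sample_conc", {
  f <- concentration_factor(100, 1, 0.5)
  expect_equal(concentration_factor(200, 1, 0.5), f / 2)
  expect_equal(concentration_factor(100, 1, 1.0), f * 2)
})

test_that("quantify_batch censors, converts units, and flags gaps", {
  cfg <- tiny_config(seed = 21, cv = 0.05)
  b <- simulate_batch(cfg)
  ratios <- response_ratios(b$peaks, b$manifest, cfg$panel)
  fits <- fit_calibrations(ratios)
  m <- quantify_batch(b$peaks, b$manifest, fits, panel = cfg$panel)
  field <- m[grepl("^f_", m$sample_id), ]
  truth <- b$truth[!is.na(b$truth$true_sample_ngl), ]
  joined <- merge(field, truth, by = c("sample_id", "compound"))
  expect_equal(joined$sample_conc_ngl, joined$true_sample_ngl,
               tolerance = 0.3)
  # extract-to-sample factor: 100 g / 1.0 / 0.5 mL -> x5
  expect_equal(joined$sample_conc_ngl / joined$extract_conc_ngml,
               rep(5, nrow(joined)))
  # blank is near zero and field mass is mandatory
  blank <- m[m$sample_id == "blank1", ]
  expect_true(all(abs(blank$extract_conc_ngml) < 0.5))
  mani_bad <- b$manifest
  mani_bad$mass_g[mani_bad$sample_type == "field"][1] <- NA
  expect_error(
    quantify_batch(b$peaks, mani_bad, fits, panel = cfg$panel),
    "missing mass_g")
})

test_that("compounds without an accepted fit are not quantifiable", {
  cfg <- tiny_config(seed = 22, cv = 0.05)
  b <- simulate_batch(cfg)
  fits <- fit_calibrations(response_ratios(b$peaks, b$manifest, cfg$panel),
                           min_r2 = 0)
  fits$accepted[fits$compound == "drugB"] <- FALSE
  m <- quantify_batch(b$peaks, b$manifest, fits, panel = cfg$panel)
  expect_true(all(m$status[m$compound == "drugB"] == "not_quantifiable"))
  expect_true(all(is.na(m$extract_conc_ngml[m$compound == "drugB"])))
  expect_false(any(m$status[m$compound == "drugA"] == "not_quantifiable"))
})

test_that("QC accuracy and precision gates match their definitions", {
  mk <- function(measured) {
    list(
      measurements = tibble::tibble(
        batch_id = "b1", sample_id = paste0("qc", seq_along(measured)),
        compound = "drugA", extract_conc_ngml = measured,
        sample_conc_ngl = NA_real_, status = "quantified",
        lod_ngl = NA_real_, loq_ngl = NA_real_, qc_pass = NA),
      manifest = validate_manifest(tibble::tibble(
        sample_id = paste0("qc", seq_along(measured)),
        sample_type = "qc_spiked", nominal_ngml = 100,
        mass_g = NA_real_, density_g_per_ml = 1,
        site_id = NA_character_, collected_on = as.Date(NA),
        replicate_group = NA_character_, sorbent = NA_character_)))
  }
  x <- mk(c(110, 110, 110))
  r <- qc_evaluate(x$measurements, x$manifest)
  expect_equal(r$accuracy_pct, 110)
  expect_true(r$accuracy_pass)
  expect_equal(r$rsd_pct, 0)
  expect_true(r$precision_pass)

  x <- mk(c(79, 79, 79))
  r <- qc_evaluate(x$measurements, x$manifest)
  expect_equal(r$accuracy_pct, 79)
  expect_false(r$accuracy_pass)

  # boundary: exactly 80 and 120 are inside the band
  expect_true(qc_evaluate(mk(c(80, 80))$measurements,
                          mk(c(80, 80))$manifest)$accuracy_pass)
  expect_true(qc_evaluate(mk(c(120, 120))$measurements,
                          mk(c(120, 120))$manifest)$accuracy_pass)

  x <- mk(100)
  expect_error(qc_evaluate(x$measurements, x$manifest), ">= 2")
  x <- mk(c(100, 100))
  x$manifest$nominal_ngml <- 0
  expect_error(qc_evaluate(x$measurements, x$manifest), "nonzero")
})

test_that("a failed QC flags every measurement without deleting any", {
  cfg <- tiny_config(seed = 23, cv = 0.05)
  b <- simulate_batch(cfg)
  fits <- fit_calibrations(response_ratios(b$peaks, b$manifest, cfg$panel))
  m <- quantify_batch(b$peaks, b$manifest, fits, panel = cfg$panel)
  qc <- qc_evaluate(m, b$manifest)
  qc$accuracy_pass[1] <- FALSE
  flagged <- set_qc_flag(m, qc)
  expect_equal(nrow(flagged), nrow(m))
  expect_true(all(!flagged$qc_pass))
})

test_that("run queue is a seeded permutation", {
  ids <- sprintf("s%02d", 1:20)
  q1 <- build_run_queue(ids, seed = 5)
  q2 <- build_run_queue(ids, seed = 5)
  expect_identical(q1, q2)
  expect_setequal(q1, ids)
  q3 <- build_run_queue(ids, seed = 6)
  expect_false(identical(q1, q3))
})

test_that("censoring substitution policies behave as documented", {
  conc <- c(100, NA, 50)
  status <- c("quantified", "below_lod", "quantified")
  lod <- c(1, 4, 1)
  expect_equal(substitute_censored(conc, status, lod, "half_lod"),
               c(100, 2, 50))
  expect_equal(substitute_censored(conc, status, lod, "zero"),
               c(100, 0, 50))
  expect_equal(substitute_censored(conc, status, lod, "lod_sqrt2"),
               c(100, 4 / sqrt(2), 50))
  expect_equal(substitute_censored(conc, status, lod, "exclude"),
               c(100, 50))
})
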