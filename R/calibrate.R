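#' Default isotope-dilution calibration design
#'
#' 22 levels spaced geometrically between 0.001 and 200 ng/mL, the working
#' range of the targeted method. Spanning more than five orders of
#' magnitude is what motivates the default 1/x weighting in
#' [fit_calibration()].
#'
#' @param n_levels number of calibrant levels.
#' @param min_level,max_level range endpoints in ng/mL.
#' @return Increasing numeric vector of nominal concentrations (ng/mL).
#' @export
default_calibration_levels <- function(n_levels = 22, min_level = 0.001,
                                       max_level = 200) {
  stopifnot(n_levels >= 3, min_level > 0, max_level > min_level)
  10^seq(log10(min_level), log10(max_level), length.out = n_levels)
}

#' Isotope-dilution response ratios
#'
#' For each native analyte and sample, the response is the quantifier peak
#' area of the native divided by the quantifier area of its assigned
#' labelled internal standard. Because both species share the injection and
#' the matrix, common-mode effects (injection volume, ionization
#' suppression) cancel in the ratio. Samples whose IS area is zero are
#' excluded with a warning; natives whose IS record is absent from a sample
#' are skipped for that sample.
#'
#' @param peaks peak tibble ([read_peak_table()] shape).
#' @param manifest sample manifest ([read_manifest()] shape).
#' @param panel a `wbe_panel`.
#' @param sample_types which manifest sample types to form ratios for.
#' @return Tibble with `sample_id`, `compound`, `ratio` and, where the
#'   manifest provides it, `nominal_ngml`.
#' @export
response_ratios <- function(peaks, manifest, panel,
                            sample_types = "calibrant") {
  keep <- manifest[manifest$sample_type %in% sample_types, , drop = FALSE]
  quant <- peaks[peaks$transition == "quant" &
                   peaks$sample_id %in% keep$sample_id, , drop = FALSE]
  nat <- panel$natives[, c("name", "is_name")]
  native_peaks <- quant[quant$compound %in% nat$name, , drop = FALSE]
  is_peaks <- quant[quant$compound %in% panel$standards$name, , drop = FALSE]
  is_areas <- is_peaks %>%
    select(sample_id = "sample_id", is_name = "compound",
           is_area = "area")
  out <- native_peaks %>%
    left_join(nat, by = c(compound = "name")) %>%
    left_join(is_areas, by = c("sample_id", "is_name"))
  missing_is <- out[is.na(out$is_area), , drop = FALSE]
  if (nrow(missing_is) > 0) {
    warn(paste0("no internal-standard peak for ",
                paste(unique(missing_is$compound), collapse = ", "),
                " in some samples; those ratios are dropped"))
    out <- out[!is.na(out$is_area), , drop = FALSE]
  }
  zero_is <- out$is_area <= 0
  if (any(zero_is)) {
    warn(paste0("internal-standard area is zero for ",
                sum(zero_is), " record(s); excluded from ratios"))
    out <- out[!zero_is, , drop = FALSE]
  }
  out$ratio <- out$area / out$is_area
  out %>%
    select("sample_id", "compound", "ratio") %>%
    left_join(keep[, c("sample_id", "nominal_ngml")], by = "sample_id")
}

#' Fit one isotope-dilution calibration curve
#'
#' Weighted least-squares line `ratio = slope * conc + intercept`. The
#' default 1/x weighting keeps the low end of a five-orders-of-magnitude
#' range from being swamped by the top calibrants; `none` and `1/x^2` are
#' selectable. R-squared is computed on the weighted fit and the curve is
#' `accepted` when it meets `min_r2` (default 0.995, the stricter of the
#' two acceptance bars in routine use; 0.99 is selectable) and has a
#' positive slope.
#'
#' @param conc nominal concentrations (ng/mL), at least 3 distinct levels.
#' @param ratio observed response ratios, same length.
#' @param weighting `"1/x"`, `"none"` or `"1/x^2"`.
#' @param min_r2 acceptance threshold on the weighted R-squared.
#' @param compound optional analyte label carried into the result.
#' @return One-row tibble of class `wbe_calfit`: `compound`, `slope`,
#'   `intercept`, `slope_se` (heteroscedasticity-robust, leverage-adjusted
#'   sandwich estimate), `weighting`, `r_squared`, `level_min`,
#'   `level_max`, `n_levels`, `accepted`.
#' @export
fit_calibration <- function(conc, ratio, weighting = c("1/x", "none", "1/x^2"),
                            min_r2 = 0.995, compound = NA_character_) {
  weighting <- match.arg(weighting)
  ok <- !is.na(conc) & !is.na(ratio)
  conc <- conc[ok]; ratio <- ratio[ok]
  if (length(unique(conc)) < 3) {
    abort("calibration requires at least 3 distinct levels")
  }
  if (any(conc <= 0)) abort("calibration levels must be > 0")
  if (sd(conc) == 0) abort("zero variance in calibration levels")
  w <- switch(weighting,
              "none" = rep(1, length(conc)),
              "1/x" = 1 / conc,
              "1/x^2" = 1 / conc^2)
  fit <- lm(ratio ~ conc, weights = w)
  sse <- sum(w * resid(fit)^2)
  sst <- sum(w * (ratio - weighted.mean(ratio, w))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  slope <- unname(coef(fit)[2])
  # Leverage-adjusted (HC3) sandwich SE: the chosen weights need not match
  # the true error variance (multiplicative noise grows faster than 1/x),
  # so the model-based SE would understate the slope uncertainty.
  X <- cbind(1, conc)
  bread <- solve(crossprod(X, w * X))
  hat <- diag(X %*% bread %*% t(w * X))
  meat <- crossprod(X, w^2 * (resid(fit) / (1 - hat))^2 * X)
  slope_se_robust <- sqrt((bread %*% meat %*% bread)[2, 2])
  res <- tibble(
    compound = compound,
    slope = slope,
    intercept = unname(coef(fit)[1]),
    slope_se = slope_se_robust,
    weighting = weighting,
    r_squared = r2,
    level_min = min(conc),
    level_max = max(conc),
    n_levels = length(unique(conc)),
    accepted = !is.na(r2) && r2 >= min_r2 && slope > 0
  )
  class(res) <- c("wbe_calfit", class(res))
  res
}

#' Fit calibration curves for every compound in a ratio table
#'
#' @param ratios output of [response_ratios()] on calibrant samples, with
#'   `nominal_ngml` populated.
#' @inheritParams fit_calibration
#' @return Tibble with one `wbe_calfit` row per compound; compounds whose
#'   calibrants cannot support a fit are skipped with a warning.
#' @export
fit_calibrations <- function(ratios, weighting = c("1/x", "none", "1/x^2"),
                             min_r2 = 0.995) {
  weighting <- match.arg(weighting)
  fits <- list()
  for (cmp in unique(ratios$compound)) {
    sub <- ratios[ratios$compound == cmp, , drop = FALSE]
    fit <- tryCatch(
      fit_calibration(sub$nominal_ngml, sub$ratio, weighting = weighting,
                      min_r2 = min_r2, compound = cmp),
      error = function(e) {
        warn(paste0("calibration for ", cmp, " failed: ",
                    conditionMessage(e)))
        NULL
      })
    if (!is.null(fit)) fits[[cmp]] <- fit
  }
  bind_rows(fits)
}

#' Predict the response ratio at a concentration
#'
#' @param fit one-row `wbe_calfit` tibble.
#' @param conc concentration(s) in ng/mL.
#' @return Predicted response ratio(s).
#' @export
predict_ratio <- function(fit, conc) {
  fit$intercept + fit$slope * conc
}

#' Invert a calibration curve (inverse prediction)
#'
#' `conc = (ratio - intercept) / slope`. Refuses unaccepted fits. Negative
#' predictions (ratio below the intercept) are returned as-is; downstream
#' censoring turns them into below-LOD results.
#'
#' @param fit one-row `wbe_calfit` tibble; must be `accepted`.
#' @param ratio observed response ratio(s).
#' @return Extract concentration(s) in ng/mL.
#' @export
invert_calibration <- function(fit, ratio) {
  if (!isTRUE(fit$accepted)) {
    abort(paste0("refusing to invert unaccepted calibration",
                 if (!is.na(fit$compound)) paste0(" for ", fit$compound)))
  }
  (ratio - fit$intercept) / fit$slope
}
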