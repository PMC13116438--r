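# Small in-code fixtures shared across the suite.

tiny_panel <- function() {
  new_panel(
    natives = tibble::tibble(
      name = c("drugA", "drugB", "metA"),
      class = c("stimulant", "opioid", "stimulant"),
      mw = c(150, 300, 120),
      role = c("parent", "parent", "metabolite"),
      parent = c(NA, NA, "drugA"),
      excretion_fraction = c(0.5, NA, 0.25),
      is_name = c("drugA-d3", "drugB-d5", "drugA-d3")),
    standards = tibble::tibble(
      name = c("drugA-d3", "drugB-d5"),
      analog_of = c("drugA", "drugB")))
}

# A noise-free two-compound batch configuration on the tiny panel;
# any sim_config() argument can be overridden through `...`.
tiny_config <- function(seed = 1, cv = 0, ...) {
  args <- list(seed = seed, compounds = c("drugA", "drugB"),
               panel = tiny_panel(), noise_cv = cv,
               suppression_range = c(1, 1), n_sites = 2, n_weeks = 2,
               true_field_conc = c(drugA = 400, drugB = 800))
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
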