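# Shared fixtures: a scaled-down trial config for unit tests (full default
# size is exercised in the acceptance suite) and quiet generation that
# swallows the clamp-rate diagnostic where it is irrelevant to the property
# under test.

small_config <- function(seed = 1L, ...) {
  sim_config(n_pairs = 2L, eas_per_community = 4L, ea_size_mean = 20,
             ea_size_sd = 2, ea_size_range = c(14L, 26L), seed = seed, ...)
}

gen_quiet <- function(cfg, items = FALSE) {
  suppressWarnings(generate_trial(cfg, items = items))
}

# Latent community-norm exposure: EA prevalence (percent) of the latent
# violence-accepting attitude among the respondent's own (single-sex) EA,
# entered per 10 percentage points. Used by simulation-recovery tests, where
# the item-derived indicator equals the latent by construction.
attach_latent_norm <- function(frame, followup) {
  sx <- unique(frame$sex)
  f <- followup[followup$sex == sx, ]
  prev <- tapply(f$accepts_violence, f$ea_id, mean) * 100
  frame$med_norm <- as.numeric(prev[frame$ea_id]) / 10
  frame
}

write_yaml_config <- function(text) {
  path <- tempfile(fileext = ".yaml")
  writeLines(text, path)
  path
}
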