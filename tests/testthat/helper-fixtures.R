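# Shared fixtures, built in code at test time.

# A reduced cohort configuration for fast unit tests.
small_config <- function(replicates = 3, ...) {
  cohort_config(replicates = replicates, image_size = c(24, 32), ...)
}

# The default virtual study, computed once and reused by the tests that
# exercise full-cohort behaviour.
.study_cache <- new.env(parent = emptyenv())
default_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- run_study(study_config())
  .study_cache$study
}

# A deterministic vegetation-like test spectrum.
test_plant_spectrum <- function(ndvi = 0.686, nitrogen = 2.4) {
  generate_plant_spectrum(ndvi, nitrogen)
}
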