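# Shared fixtures, built in code and memoized across test files so that
# expensive cohort simulations run once per suite.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Small noise-free configuration: 2 subjects per arm, days 0-6, quiet
# instrument, 48 px grid. Deterministic end to end.
zero_noise_config <- function(n_px = 48, days = 0:6) {
  inst <- instrument_model(n_px = n_px, noise_frac = 0, drift_sd = 0)
  cohort_config(
    n_per_group = c(Control = 2, CPA = 2, `CPA+Ab` = 2),
    days = days,
    baseline_cv = list(volume = 0, a = 0, b = 0, ctHbO2 = 0, ctHHb = 0),
    subject_sd = 0,
    day_noise_sd = c(a = 0, b = 0, ctHbO2 = 0, ctHHb = 0, volume = 0),
    caliper_cv = 0, aspect_sd = 0,
    instrument = inst, seed = 7L)
}

zero_noise_table <- function() {
  fixture("zero_noise_table", {
    coh <- generate_cohort(zero_noise_config())
    process_cohort(coh)
  })
}

# Default-condition cohorts at the study's calibrated noise, full imaging
# pipeline, one table per seed. Used by the acceptance checks.
acceptance_tables <- function(seeds = 1:10) {
  fixture("acceptance_tables", {
    lapply(seeds, function(s) {
      coh <- generate_cohort(cohort_config(seed = s))
      tab <- process_cohort(coh)
      rm(coh); gc(verbose = FALSE)
      tab
    })
  })
}

default_luts <- function() {
  fixture("default_luts", build_luts(cohort_config()))
}

default_ext <- function() {
  fixture("default_ext", load_extinction_table())
}

## Build an sfdi_props object directly from biomarker ground truth.
props_from_biomarkers <- function(a, b, ctHbO2, ctHHb, n = 8,
                                  wl = c(659, 691, 731, 851),
                                  ext = default_ext()) {
  musp <- scatter_power_law(a, b, wl)
  mua <- mua_from_chromophores(ctHbO2, ctHHb, wl, ext)
  obj <- list(mua = array(rep(mua, each = n * n), c(n, n, 4)),
              musp = array(rep(musp, each = n * n), c(n, n, 4)),
              valid = array(TRUE, c(n, n, 4)),
              wavelengths = wl, n_px = n)
  class(obj) <- "sfdi_props"
  obj
}

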