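# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no binary data.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_registry <- function() fixture("registry", build_default_registry)

# noiseless standard mix and its calibration
fx_std_clean <- function() fixture("std_clean", function() {
  simulate_chromatogram(
    make_preset("standard_mix"),
    sim_config(intensity_noise_cv = 0, mz_jitter_sd = 0, seed = 1),
    fx_registry()
  )
})

fx_factors <- function() fixture("factors", function() {
  calibrate_response(fx_std_clean(), fx_registry())
})

# noiseless wild-type run and its picked peaks
fx_wt_clean <- function() fixture("wt_clean", function() {
  simulate_chromatogram(
    make_preset("wild_type"),
    sim_config(intensity_noise_cv = 0, mz_jitter_sd = 0, seed = 1),
    fx_registry()
  )
})

fx_wt_clean_peaks <- function() fixture("wt_clean_peaks", function() {
  pick_sample_peaks(fx_wt_clean(), fx_registry())
})

# independent atomic masses for oracle sums (typed afresh from IUPAC
# tables, not read from package internals)
ORACLE_MASS <- c(C = 12, H = 1.00782503207, O = 15.9949146196,
                 N = 14.0030740048, Na = 22.9897692809, K = 38.96370668)

oracle_formula_mass <- function(counts) {
  sum(ORACLE_MASS[names(counts)] * counts)
}

# group label for a CE species, mirroring the published grouped reporting
oracle_ce_label_id <- function(n, d) {
  pairs <- list(
    `1` = list(c(10, 0)), `2` = list(c(12, 0), c(14, 1)),
    `3` = list(c(14, 0), c(16, 1)), `4` = list(c(15, 0)),
    `5` = list(c(16, 0), c(18, 1)), `6` = list(c(17, 0)),
    `7` = list(c(18, 0), c(20, 1)), `8` = list(c(19, 0)),
    `9` = list(c(20, 0), c(22, 1)), `10` = list(c(21, 0)),
    `11` = list(c(22, 0), c(24, 1)), `12` = list(c(23, 0)),
    `13` = list(c(24, 0), c(26, 1)), `14` = list(c(25, 0)),
    `15` = list(c(26, 0), c(28, 1)), `16` = list(c(27, 0)),
    `17` = list(c(28, 0), c(30, 1)), `18` = list(c(29, 0)),
    `19` = list(c(30, 0), c(32, 1)), `20` = list(c(34, 1))
  )
  for (id in names(pairs)) {
    for (p in pairs[[id]]) {
      if (p[1] == n && p[2] == d) return(as.integer(id))
    }
  }
  21L
}
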