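# helper: a bare trace object without running the simulator
toy_trace <- function(rt, intensity, target_mz = 500, window_mda = 50) {
  out <- tibble::tibble(rt_min = rt, intensity = intensity)
  attr(out, "target_mz") <- target_mz
  attr(out, "window_mda") <- window_mda
  class(out) <- c("eic_trace", class(out))
  out
}

test_that("EIC window is a closed interval of the stated total width", {
  s <- scan_set(
    tibble::tibble(scan = 1:3, rt_min = c(1, 2, 3)),
    tibble::tibble(
      scan = c(1L, 2L, 3L, 3L),
      mz = c(500.025, 500.0251, 499.975, 500.000), # edge, outside, edge, in
      intensity = c(10, 20, 30, 40)
    )
  )
  tr <- extract_eic(s, list(target_mz = 500, window_mda = 50))
  expect_equal(tr$intensity, c(10, 0, 70)) # edges included, outside not
})

test_that("widening the window never decreases any EIC intensity", {
  cfg <- sim_config(rt_end = 10, seed = 31)
  s <- simulate_chromatogram(make_preset("standard_mix"), cfg, fx_registry())
  for (mz in c(369.3521, 619.6393)) {
    prev <- rep(0, n_scans(s))
    for (w in c(10, 25, 50, 100, 500)) {
      cur <- extract_eic(s, list(target_mz = mz, window_mda = w))$intensity
      expect_true(all(cur >= prev - 1e-9))
      prev <- cur
    }
  }
})

test_that("integration matches the analytic Gaussian area", {
  rt <- seq(0, 10, by = 0.01)
  h <- 5000; s <- 0.12; mu <- 5
  tr <- toy_trace(rt, 40 + h * exp(-(rt - mu)^2 / (2 * s^2)))
  pk <- detect_and_integrate(tr)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$area, h * s * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(pk$rt_apex, mu, tolerance = 0.005)

  # two baseline-separated Gaussians, each within 1% of its analytic area
  h2 <- 1200; mu2 <- 8
  tr2 <- toy_trace(rt, 40 + h * exp(-(rt - mu)^2 / (2 * s^2)) +
                     h2 * exp(-(rt - mu2)^2 / (2 * s^2)))
  pk2 <- detect_and_integrate(tr2)
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$area[1], h * s * sqrt(2 * pi), tolerance = 0.01)
  expect_equal(pk2$area[2], h2 * s * sqrt(2 * pi), tolerance = 0.01)
})

test_that("flat and empty traces yield no peaks", {
  rt <- seq(0, 5, by = 0.02)
  expect_equal(nrow(detect_and_integrate(toy_trace(rt, rep(80, length(rt))))),
               0)
  expect_equal(nrow(detect_and_integrate(toy_trace(rt, rep(0, length(rt))))),
               0)
})

test_that("peak areas scale linearly with intensity", {
  rt <- seq(0, 10, by = 0.01)
  set.seed(99)
  y <- 40 + 3000 * exp(-(rt - 4)^2 / (2 * 0.1^2)) + rnorm(length(rt), 0, 2)
  a1 <- detect_and_integrate(toy_trace(rt, y))$area
  a2 <- detect_and_integrate(toy_trace(rt, 3 * y))$area
  expect_equal(a2 / a1, 3, tolerance = 1e-9)
})

test_that("calibration recovers the embedded response factors", {
  fac <- fx_factors()
  expect_equal(fac$factor[fac$species_id == "Chl"], 1.00)
  expect_equal(fac$factor[fac$species_id == "CE 18:1"], 2.21,
               tolerance = 1e-5)
  expect_equal(fac$factor[fac$species_id == "CE 24:1"], 2.41,
               tolerance = 1e-5)
})

test_that("response factors are invariant to mixture concentration", {
  reg <- fx_registry()
  cfg <- sim_config(intensity_noise_cv = 0, mz_jitter_sd = 0, seed = 1)
  half <- dplyr::mutate(make_preset("standard_mix"), amount = amount / 2)
  fac_half <- calibrate_response(simulate_chromatogram(half, cfg, reg), reg)
  expect_equal(fac_half$factor, fx_factors()$factor, tolerance = 1e-6)
})

test_that("equal embedded responses give unit factors", {
  reg <- fx_registry()
  cfg <- sim_config(intensity_noise_cv = 0, mz_jitter_sd = 0, seed = 1)
  flat <- dplyr::mutate(make_preset("standard_mix"), response_factor = 1)
  fac <- calibrate_response(simulate_chromatogram(flat, cfg, reg), reg)
  expect_equal(fac$factor, rep(1, nrow(fac)), tolerance = 1e-5)
})

test_that("calibration without a cholesterol peak is an error", {
  reg <- fx_registry()
  cfg <- sim_config(rt_start = 15, rt_end = 30,
                    intensity_noise_cv = 0, mz_jitter_sd = 0, seed = 1)
  no_chl <- make_preset("standard_mix")
  no_chl <- no_chl[no_chl$species_id != "Chl", ]
  s <- simulate_chromatogram(no_chl, cfg, reg)
  expect_error(calibrate_response(s, reg), "cholesterol")
})

test_that("sterol ratio handles the no-CE and all-zero edge cases", {
  peaks <- tibble::tibble(
    adduct = "M-H2O+H", target_mz = 369.3521, rt_apex = 6.93,
    area = 1000, height = 4000, snr = 100, label = "Chl",
    label_id = NA_integer_, lipid_class = "Chl"
  )
  expect_equal(chl_ce_ratio(peaks), 100) # no CE at all
  expect_error(chl_ce_ratio(peaks[0, ]), "no sterol")
})

test_that("CE peaks below the quantitation limit contribute nothing", {
  reg <- fx_registry()
  cfg <- sim_config(intensity_noise_cv = 0.02, mz_jitter_sd = 0, seed = 17)
  # cholesterol plus one just-detectable trace ester
  comp <- tibble::tibble(
    species_id = c("Chl", "CE 18:0"),
    amount = c(50, 1.5e-5),
    response_factor = c(1, 2.27),
    fragment_yield = c(1, 1)
  )
  s <- simulate_chromatogram(comp, cfg, reg)
  pks <- pick_sample_peaks(s, reg, min_snr = 3)
  ce <- pks[pks$adduct == "M-H2O+H" & !is.na(pks$label_id), ]
  expect_gte(nrow(ce), 1)
  expect_true(all(ce$snr < 10))
  expect_equal(chl_ce_ratio(pks, fx_factors(), lloq_snr = 10), 100)
  expect_lt(chl_ce_ratio(pks, fx_factors(), lloq_snr = 0), 100)
})

test_that("chain profiles are normalized and complete", {
  pks <- fx_wt_clean_peaks()
  for (mode in c("adduct", "fragment")) {
    prof <- chain_profile(pks, mode)
    expect_equal(sum(prof$percent), 100, tolerance = 1e-9)
    expect_true(all(prof$percent >= 0))
  }
  # single-species input: that label at 100%
  one <- pks[pks$adduct == "M+H" & pks$label == "C26:0/C28:1-CE", ][1, ]
  expect_equal(chain_profile(one, "adduct")$percent, 100)
})

test_that("class balance is normalized and respects single-class input", {
  pks <- fx_wt_clean_peaks()
  bal <- class_balance(pks, fx_factors())
  expect_equal(sum(bal$percent), 100, tolerance = 1e-9)
  expect_setequal(bal$lipid_class, c("Chl", "CE", "WE", "TAG"))
  we_only <- pks[pks$lipid_class == "WE", ]
  bal_we <- class_balance(we_only)
  expect_equal(bal_we$percent[bal_we$lipid_class == "WE"], 100)
  expect_error(class_balance(pks[0, ]), "no class signal")
})

test_that("group comparison reports means, SDs and Welch p-values", {
  d <- tibble::tibble(genotype = rep(c("a", "b"), each = 7),
                      value = c(rep(5, 7), rep(5, 7)))
  res <- compare_groups(d)
  expect_equal(res$comparisons$p_value, 1)
  expect_equal(res$comparisons$t, 0)
  expect_equal(res$summary$mean, c(5, 5))

  set.seed(1)
  d2 <- tibble::tibble(genotype = rep(c("a", "b"), each = 7),
                       value = c(rnorm(7, 0, 1), rnorm(7, 5, 1)))
  res2 <- compare_groups(d2)
  expect_lt(res2$comparisons$p_value, 0.001)
  expect_equal(res2$summary$mean[res2$summary$group == "a"],
               mean(d2$value[d2$genotype == "a"]))
  expect_error(compare_groups(d2[c(1, 8:14), ]), "at least 2")
})
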