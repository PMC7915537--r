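# Generator-side ionization model for the common sterol fragment channel:
# relative response per mole, cholesterol = 1.00, with CE response linear in
# equivalent carbon number (ECN = FA carbons - 2 x double bonds) through the
# two calibrated standards (cholesteryl oleate 2.21 at ECN 16, cholesteryl
# nervonate 2.41 at ECN 22). Co-eluting Cn:0 / C(n+2):1 esters share an ECN
# and hence a response.
sterol_response_line <- function(ecn) {
  2.21 + (2.41 - 2.21) / 6 * (ecn - 16)
}

#' Composition presets for synthetic meibum chromatograms
#'
#' Returns a composition table: one row per species with its molar amount
#' (arbitrary molar units), per-species relative ionization response
#' (signal per mole, cholesterol = 1) and the fraction of that signal
#' appearing on the common sterol fragment channel at m/z 369.35.
#'
#' Presets:
#' \describe{
#'   \item{wild_type}{Cholesterol at 7% of total sterol molar amount
#'     (cholesterol + CE); all 50 CE present, chain distribution a smooth
#'     unimodal shape over equivalent carbon number peaking near C25 with
#'     monounsaturated esters dominant; WE-dominant class profile with a
#'     modest TAG share and a minor Chl-OAHFA component.}
#'   \item{het}{Identical to `wild_type` (heterozygotes are
#'     indistinguishable from wild type in lipid composition).}
#'   \item{soat1_null}{CE with fatty-acid chains longer than C20 absent;
#'     C16-C20 esters at trace amounts far below quantitation limits; free
#'     cholesterol dominant; TAG share roughly doubled, WE somewhat
#'     reduced; no Chl-OAHFA.}
#'   \item{standard_mix}{Equimolar cholesterol, cholesteryl oleate (CE
#'     18:1), cholesteryl nervonate (CE 24:1), triolein (TAG 54:3) and
#'     lignoceryl oleate (WE 42:1), with sterol-channel responses
#'     1.00/2.21/2.41 for Chl/CO/CN.}
#' }
#'
#' @param name One of `"wild_type"`, `"het"`, `"soat1_null"`,
#'   `"standard_mix"`.
#' @return Tibble with columns `species_id`, `amount`, `response_factor`,
#'   `fragment_yield`.
#' @export
make_preset <- function(name = c("wild_type", "het", "soat1_null",
                                 "standard_mix")) {
  name <- match.arg(name)
  if (name == "het") name <- "wild_type"

  ce_grid <- expand.grid(n = 10:34, d = 0:1)
  ce_ids <- sprintf("CE %d:%d", ce_grid$n, ce_grid$d)
  ce_rf <- sterol_response_line(ce_grid$n - 2 * ce_grid$d)

  if (name == "standard_mix") {
    return(tibble::tibble(
      species_id = c("Chl", "CE 18:1", "CE 24:1", "TAG 54:3", "WE 42:1"),
      amount = 1,
      response_factor = c(1.00, 2.21, 2.41, 1.00, 1.00),
      fragment_yield = c(1, 1, 1, 0, 0)
    ))
  }

  we_ids <- sprintf("WE %d:%d", c(42, 43, 44, 46, 48, 50),
                    c(1, 1, 1, 1, 2, 2))
  we_shape <- c(0.40, 0.15, 0.15, 0.12, 0.10, 0.08)
  tag_ids <- c("TAG 52:3", "TAG 54:3")

  if (name == "wild_type") {
    # CE chain distribution: Gaussian in ECN centered at 25, sd 4;
    # monounsaturated species carry 80% of each ECN's weight
    ecn <- ce_grid$n - 2 * ce_grid$d
    w <- exp(-(ecn - 25)^2 / (2 * 4^2)) * ifelse(ce_grid$d == 1, 0.8, 0.2)
    ce_amt <- 93 * w / sum(w) # total CE 93 molar units, Chl 7 -> 7% sterol
    return(tibble::tibble(
      species_id = c("Chl", ce_ids, we_ids, tag_ids, "Chl-OAHFA 50:2"),
      amount = c(7, ce_amt, 140 * we_shape, c(15, 10), 3),
      response_factor = c(1, ce_rf, rep(1, length(we_ids)), 1, 1,
                          sterol_response_line(46)),
      fragment_yield = c(1, rep(1, length(ce_ids)),
                         rep(0, length(we_ids)), 0, 0, 1)
    ))
  }

  # soat1_null: CE > C20 obliterated; C16-C20 at trace; Chl dominant
  ce_amt <- numeric(length(ce_ids))
  trace <- ce_grid$n >= 16 & ce_grid$n <= 20
  ce_amt[trace] <- 1e-5
  tibble::tibble(
    species_id = c("Chl", ce_ids, we_ids, tag_ids),
    amount = c(40, ce_amt, 40 * we_shape, c(12, 8)),
    response_factor = c(1, ce_rf, rep(1, length(we_ids)), 1, 1),
    fragment_yield = c(1, rep(1, length(ce_ids)), rep(0, length(we_ids)),
                       0, 0)
  )
}

#' Simulation configuration
#'
#' @param rt_start,rt_end,rt_step Retention-time grid in minutes.
#' @param peak_width_sigma Gaussian elution peak sigma in minutes.
#' @param mz_jitter_sd Centroid m/z jitter standard deviation in mDa.
#' @param intensity_noise_cv Multiplicative intensity noise coefficient of
#'   variation (fraction).
#' @param baseline_level Additive chemical baseline, counts.
#' @param signal_per_mole Counts x min of peak area per molar unit at unit
#'   response factor.
#' @param seed Integer seed; required, simulations are deterministic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(rt_start = 0, rt_end = 45, rt_step = 0.02,
                       peak_width_sigma = 0.1, mz_jitter_sd = 3,
                       intensity_noise_cv = 0.02, baseline_level = 100,
                       signal_per_mole = 1e5, seed) {
  if (missing(seed)) stop("a seed is required for simulation", call. = FALSE)
  stopifnot(rt_step > 0, peak_width_sigma > 0, intensity_noise_cv >= 0,
            mz_jitter_sd >= 0, baseline_level >= 0, rt_end > rt_start)
  structure(list(
    rt_start = rt_start, rt_end = rt_end, rt_step = rt_step,
    peak_width_sigma = peak_width_sigma, mz_jitter_sd = mz_jitter_sd,
    intensity_noise_cv = intensity_noise_cv,
    baseline_level = baseline_level, signal_per_mole = signal_per_mole,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a centroided LC-MS chromatogram
#'
#' Every registry channel of every species in the composition emits a
#' Gaussian elution profile centred at the species' nominal retention time
#' with total area `amount x response_factor x signal_per_mole` (scaled by
#' `fragment_yield` on the shared m/z 369.35 sterol channel). Channels that
#' share a target m/z (the sterol fragment) are summed into one centroid
#' per scan. A constant chemical baseline is added on every monitored
#' channel, multiplicative Gaussian noise is applied to intensities, and
#' centroid m/z values are jittered. Deterministic for a fixed seed.
#'
#' @param comp Composition tibble from [make_preset()] (columns
#'   `species_id`, `amount`, `response_factor`, `fragment_yield`).
#' @param cfg A [sim_config()].
#' @param registry A [build_default_registry()] table; all composition
#'   species must be present with a retention time.
#' @return A [scan_set()].
#' @export
simulate_chromatogram <- function(comp, cfg, registry = build_default_registry()) {
  stopifnot(inherits(cfg, "sim_config"))
  missing_sp <- setdiff(comp$species_id, registry$id)
  if (length(missing_sp) > 0) {
    stop("species not in registry: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  rt <- seq(cfg$rt_start, cfg$rt_end, by = cfg$rt_step)
  nscan <- length(rt)

  # one simulated trace per unique channel m/z (sterol fragment collapses)
  chan <- dplyr::distinct(registry[, c("target_mz")])
  chan$channel <- seq_len(nrow(chan))
  reg <- dplyr::left_join(tibble::as_tibble(registry), chan,
                          by = "target_mz")
  emit <- dplyr::inner_join(reg, comp, by = c("id" = "species_id"))

  signal <- matrix(0, nrow = nscan, ncol = nrow(chan))
  for (i in seq_len(nrow(emit))) {
    e <- emit[i, ]
    yield <- if (e$adduct == "M-H2O+H") e$fragment_yield else 1
    area <- e$amount * e$response_factor * cfg$signal_per_mole * yield
    if (area <= 0) next
    signal[, e$channel] <- signal[, e$channel] +
      area * stats::dnorm(rt, mean = e$rt_min, sd = cfg$peak_width_sigma)
  }

  withr::with_seed(cfg$seed, {
    noise <- matrix(stats::rnorm(nscan * nrow(chan), 0,
                                 cfg$intensity_noise_cv),
                    nrow = nscan)
    jitter <- matrix(stats::rnorm(nscan * nrow(chan), 0,
                                  cfg$mz_jitter_sd / 1000),
                     nrow = nscan)
  })
  obs <- pmax((signal + cfg$baseline_level) * (1 + noise), 0)

  centroids <- tibble::tibble(
    scan = rep(seq_len(nscan), times = nrow(chan)),
    mz = rep(chan$target_mz, each = nscan) + as.vector(jitter),
    intensity = as.vector(obs)
  )
  centroids <- centroids[centroids$intensity > 0, ]
  scan_set(tibble::tibble(scan = seq_len(nscan), rt_min = rt), centroids)
}

#' Simulate a birefringence melting curve
#'
#' Evaluates the two-transition Hill melting model (see [hill_model()]) on
#' a temperature grid and adds Gaussian noise. Deterministic for a fixed
#' seed.
#'
#' @param params Hill parameter list from [hill_params()].
#' @param temp_K Strictly increasing temperature grid in Kelvin.
#' @param noise_sd Gaussian noise standard deviation, birefringence units.
#' @param seed Integer seed.
#' @return Tibble with columns `temperature_K`, `birefringence`.
#' @export
simulate_melting_curve <- function(params, temp_K, noise_sd = 0.01, seed) {
  if (missing(seed)) stop("a seed is required for simulation", call. = FALSE)
  stopifnot(noise_sd >= 0)
  if (is.unsorted(temp_K, strictly = TRUE)) {
    stop("temperature grid must be strictly increasing", call. = FALSE)
  }
  ibr <- hill_model(temp_K, params)
  if (noise_sd > 0) {
    ibr <- ibr + withr::with_seed(seed,
                                  stats::rnorm(length(temp_K), 0, noise_sd))
  }
  tibble::tibble(temperature_K = temp_K, birefringence = ibr)
}

#' Ellipse axis fixture
#'
#' Builds a semi-axis pair with unit semi-major axis and the requested
#' short-to-long axis ratio, for exercising the eye-opening morphometry.
#'
#' @param ratio Axis ratio b/a in (0, 1].
#' @return Named numeric vector `c(a = 1, b = ratio)`.
#' @export
make_ellipse_fixture <- function(ratio) {
  if (!(is.numeric(ratio) && length(ratio) == 1 && ratio > 0 && ratio <= 1)) {
    stop("ratio must be a single number in (0, 1]", call. = FALSE)
  }
  c(a = 1, b = ratio)
}

#' Simulate a full experiment with generative truth
#'
#' Convenience wrapper: simulates one chromatogram per requested replicate
#' and genotype preset, optionally writing scan CSVs and a truth sidecar
#' (the generative composition) as JSON next to them.
#'
#' @param presets Named integer vector: preset name -> number of
#'   replicates, e.g. `c(wild_type = 5, soat1_null = 5)`.
#' @param cfg A [sim_config()]; per-replicate seeds are derived from
#'   `cfg$seed`.
#' @param registry Species registry.
#' @param out_dir Optional directory; when given, scan CSVs and a
#'   `truth.json` sidecar are written there.
#' @return Tibble with columns `genotype`, `replicate`, `seed`, `scans`
#'   (list column of scan sets) and `truth` (list column of compositions).
#' @export
simulate_experiment <- function(presets, cfg,
                                registry = build_default_registry(),
                                out_dir = NULL) {
  stopifnot(length(presets) > 0, !is.null(names(presets)))
  runs <- purrr::imap_dfr(presets, function(nrep, preset) {
    tibble::tibble(genotype = preset, replicate = seq_len(nrep))
  })
  runs$seed <- cfg$seed + seq_len(nrow(runs))
  runs$truth <- purrr::map(runs$genotype, make_preset)
  runs$scans <- purrr::map2(runs$truth, runs$seed, function(comp, s) {
    cfg_i <- cfg
    cfg_i$seed <- s
    simulate_chromatogram(comp, cfg_i, registry)
  })
  if (!is.null(out_dir)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("writing a truth sidecar requires jsonlite", call. = FALSE)
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    purrr::pwalk(runs[, c("genotype", "replicate", "scans")],
                 function(genotype, replicate, scans) {
      write_scans(scans, file.path(
        out_dir, sprintf("%s_rep%02d.csv", genotype, replicate)))
    })
    jsonlite::write_json(
      purrr::map(stats::setNames(runs$truth,
                                 paste0(runs$genotype, "_rep",
                                        runs$replicate)),
                 ~ as.list(.x)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  runs
}
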