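#' Extract an ion chromatogram
#'
#' Sums, per scan, the centroid intensities falling inside the channel's
#' m/z window (total width `window_mda` mDa, i.e. `+/- window_mda/2`,
#' closed interval). Scans with no centroid in the window contribute zero.
#'
#' @param scans A [scan_set()].
#' @param channel A registry row or list with `target_mz` (Da) and
#'   `window_mda` (mDa total width).
#' @return An `eic_trace` tibble (`rt_min`, `intensity`) carrying
#'   `target_mz` and `window_mda` attributes.
#' @export
extract_eic <- function(scans, channel) {
  stopifnot(inherits(scans, "scan_set"))
  if (is.data.frame(channel)) channel <- as.list(channel[1, ])
  target <- channel$target_mz
  half <- channel$window_mda / 2000 # mDa -> Da, half-width
  cen <- scans$centroids
  hit <- cen[abs(cen$mz - target) <= half, ]
  sums <- tapply(hit$intensity, hit$scan, sum)
  intensity <- numeric(nrow(scans$scans))
  idx <- match(as.integer(names(sums)), scans$scans$scan)
  intensity[idx] <- as.numeric(sums)
  out <- tibble::tibble(rt_min = scans$scans$rt_min, intensity = intensity)
  attr(out, "target_mz") <- target
  attr(out, "window_mda") <- channel$window_mda
  class(out) <- c("eic_trace", class(out))
  out
}

# Two-pass rolling baseline. Pass 1: rolling low quantile (15th
# percentile), which stays near the baseline even when elution peaks occupy
# much of the trace, as on the shared sterol fragment channel where CE
# homologs elute every ~1.2 min. Pass 2: points materially above that
# provisional baseline are masked (with dilation to cover peak shoulders)
# and the baseline is re-estimated as a rolling median of the remaining
# peak-free points, interpolated across masked stretches. The second pass
# removes the downward bias a plain quantile picks up from peak tails.
rolling_baseline <- function(trace, window_min = 2, prob = 0.15) {
  rt <- trace$rt_min
  x <- trace$intensity
  n <- length(x)
  step <- stats::median(diff(rt))
  half <- max(1L, as.integer(round(window_min / step / 2)))
  if (2 * half + 1 >= n) {
    return(rep(stats::quantile(x, prob, names = FALSE), n))
  }
  at <- unique(c(seq(1L, n, by = max(1L, half %/% 5L)), n))
  roll_stat <- function(vals, keep, fun) {
    vapply(at, function(i) {
      w <- max(1L, i - half):min(n, i + half)
      w <- w[keep[w]]
      if (length(w) < 5) NA_real_ else fun(vals[w])
    }, numeric(1))
  }
  q1 <- roll_stat(x, rep(TRUE, n),
                  function(v) stats::quantile(v, prob, names = FALSE))
  base1 <- stats::approx(rt[at], q1, xout = rt, rule = 2)$y
  y1 <- x - base1
  nz <- trace_noise(y1)
  thr <- if (nz > 0) 3 * nz else 1e-9 * max(abs(y1), 1)
  mask <- y1 > thr
  d <- max(1L, as.integer(round(0.25 / step))) # dilate over peak shoulders
  grown <- as.logical(stats::filter(as.numeric(mask), rep(1, 2 * d + 1),
                                    sides = 2) > 0)
  grown[is.na(grown)] <- mask[is.na(grown)]
  q2 <- roll_stat(x, !grown, stats::median)
  if (all(is.na(q2))) {
    return(base1)
  }
  ok <- !is.na(q2)
  stats::approx(rt[at][ok], q2[ok], xout = rt, rule = 2)$y
}

# Robust noise level from successive differences: on a smooth trace the
# first difference cancels the signal and leaves ~N(0, 2 sigma^2) noise.
# Iterative sigma clipping discards differences dominated by peak slopes,
# which otherwise inflate the estimate on peak-dense channels.
trace_noise <- function(y) {
  if (length(y) < 3) return(0)
  d <- abs(diff(y))
  s <- 1.4826 * stats::median(d) / sqrt(2)
  for (i in 1:50) {
    keep <- d <= 4 * sqrt(2) * s
    if (s <= 0 || all(keep)) break
    s_new <- 1.4826 * stats::median(d[keep]) / sqrt(2)
    if (s_new >= s) break
    s <- s_new
  }
  s
}

#' Detect and integrate elution peaks in an EIC
#'
#' Baseline is a rolling low quantile (default 2 min window); the noise
#' level is `1.4826 x MAD` of the first differences of the
#' baseline-subtracted trace (scaled by `1/sqrt(2)`), which stays a pure
#' noise estimate even on peak-dense channels. Local maxima exceeding
#' `min_snr x noise` are peaks; each peak's integration region extends from
#' its apex down to where the baseline-subtracted signal falls below
#' `max(2 x noise, 1e-6 x height)` or to the valley shared with a neighbouring
#' peak. Areas are trapezoidal integrals of the baseline-subtracted signal
#' (counts x min).
#'
#' @param trace An [extract_eic()] trace.
#' @param min_snr Minimum apex signal-to-noise for detection (default 5;
#'   high enough that a peak-free channel yields no false maxima).
#' @param baseline_window Rolling-median window in minutes (default 2).
#' @return Tibble of peaks: `rt_apex`, `area`, `height`, `snr`,
#'   `target_mz`. Zero rows when the trace is flat.
#' @export
detect_and_integrate <- function(trace, min_snr = 5, baseline_window = 2) {
  rt <- trace$rt_min
  x <- trace$intensity
  n <- length(x)
  if (n < 3) {
    return(empty_peaks(attr(trace, "target_mz")))
  }
  base <- rolling_baseline(trace, baseline_window)
  y <- x - base
  noise <- trace_noise(y)
  ymax <- max(y)
  if (ymax <= 0) {
    return(empty_peaks(attr(trace, "target_mz")))
  }
  det_thr <- max(min_snr * noise, 1e-9 * ymax)

  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] &
                y[2:(n - 1)] > y[3:n], FALSE) & y > det_thr
  apexes <- which(is_max)
  if (length(apexes) == 0) {
    return(empty_peaks(attr(trace, "target_mz")))
  }

  # suppress shoulder maxima: within a connected above-threshold region,
  # keep maxima separated by a real valley (drop below half the lower apex)
  keep <- rep(TRUE, length(apexes))
  if (length(apexes) > 1) {
    for (i in seq_len(length(apexes) - 1)) {
      lo <- min(y[apexes[i]:apexes[i + 1]])
      small <- min(y[apexes[i]], y[apexes[i + 1]])
      if (lo > 0.5 * small) {
        if (y[apexes[i]] < y[apexes[i + 1]]) keep[i] <- FALSE
        else keep[i + 1] <- FALSE
      }
    }
    apexes <- apexes[keep]
  }

  peaks <- purrr::map_dfr(seq_along(apexes), function(j) {
    a <- apexes[j]
    h <- y[a]
    floor_thr <- max(2 * noise, 1e-6 * h)
    left_stop <- if (j > 1) apexes[j - 1] else 1L
    right_stop <- if (j < length(apexes)) apexes[j + 1] else n
    lo <- a
    while (lo > left_stop && y[lo - 1] > floor_thr) lo <- lo - 1L
    hi <- a
    while (hi < right_stop && y[hi + 1] > floor_thr) hi <- hi + 1L
    # adjacent peaks that stay above the floor are split at their valley
    if (j > 1 && lo <= apexes[j - 1]) {
      lo <- apexes[j - 1] + which.min(y[apexes[j - 1]:a]) - 1L
    }
    if (j < length(apexes) && hi >= apexes[j + 1]) {
      hi <- a + which.min(y[a:apexes[j + 1]]) - 1L
    }
    seg <- lo:hi
    yy <- pmax(y[seg], 0)
    area <- sum(diff(rt[seg]) * (utils::head(yy, -1) + utils::tail(yy, -1))) / 2
    # parabolic apex refinement: the true maximum generally falls between
    # grid points
    rt_apex <- rt[a]
    if (a > 1 && a < n) {
      denom <- y[a - 1] - 2 * y[a] + y[a + 1]
      if (denom < 0) {
        off <- 0.5 * (y[a - 1] - y[a + 1]) / denom
        if (abs(off) <= 0.5) rt_apex <- rt[a] + off * (rt[a + 1] - rt[a])
      }
    }
    tibble::tibble(
      rt_apex = rt_apex, area = area, height = h,
      snr = if (noise > 0) h / noise else Inf,
      target_mz = attr(trace, "target_mz") %||% NA_real_
    )
  })
  peaks[peaks$area > 0, ]
}

empty_peaks <- function(target_mz) {
  tibble::tibble(rt_apex = numeric(0), area = numeric(0),
                 height = numeric(0), snr = numeric(0),
                 target_mz = if (is.null(target_mz)) numeric(0) else
                   numeric(0))
}

#' Detect, integrate and assign peaks on every registry channel
#'
#' Runs [extract_eic()] and [detect_and_integrate()] for each distinct
#' (m/z, adduct) channel of the registry and assigns species labels via
#' [assign_peak()].
#'
#' @param scans A [scan_set()].
#' @param registry Species registry.
#' @param min_snr Detection threshold (see [detect_and_integrate()]).
#' @return Tibble of assigned peaks with columns `adduct`, `target_mz`,
#'   `rt_apex`, `area`, `height`, `snr`, `label`, `label_id`,
#'   `lipid_class`.
#' @export
pick_sample_peaks <- function(scans, registry = build_default_registry(),
                              min_snr = 5) {
  tab <- build_assignment_table(registry)
  channels <- dplyr::distinct(
    tibble::as_tibble(registry)[, c("target_mz", "window_mda", "adduct")])
  peaks <- purrr::map_dfr(seq_len(nrow(channels)), function(i) {
    ch <- channels[i, ]
    pk <- detect_and_integrate(extract_eic(scans, ch), min_snr = min_snr)
    if (nrow(pk) == 0) return(NULL)
    pk$adduct <- ch$adduct
    pk
  })
  if (nrow(peaks) == 0) {
    return(tibble::tibble(
      adduct = character(0), target_mz = numeric(0), rt_apex = numeric(0),
      area = numeric(0), height = numeric(0), snr = numeric(0),
      label = character(0), label_id = integer(0),
      lipid_class = character(0)
    ))
  }
  peaks$label <- purrr::map2_chr(peaks$target_mz, peaks$rt_apex,
                                 function(mz, rt) assign_peak(mz, rt, tab))
  lab_info <- dplyr::distinct(tab[, c("label", "label_id")])
  peaks <- dplyr::left_join(peaks, lab_info, by = "label")
  class_of <- c(stats::setNames(registry$lipid_class, registry$id))
  peaks$lipid_class <- dplyr::case_when(
    peaks$label == "Chl" ~ "Chl",
    !is.na(peaks$label_id) ~ "CE",
    peaks$label %in% names(class_of) ~ unname(class_of[peaks$label]),
    TRUE ~ "unknown"
  )
  peaks[, c("adduct", "target_mz", "rt_apex", "area", "height", "snr",
            "label", "label_id", "lipid_class")]
}

#' Calibrate relative response factors from an equimolar standard run
#'
#' Integrates the standard-mix chromatogram and expresses each standard's
#' peak area relative to free cholesterol. Sterol standards (cholesterol,
#' cholesteryl oleate, cholesteryl nervonate) are read off the shared
#' m/z 369.35 fragment channel; the non-sterol standards (triolein,
#' lignoceryl oleate) off their proton-adduct channels. Cholesterol is 1.00
#' by definition.
#'
#' @param standard_scans [scan_set()] of the equimolar standard mixture.
#' @param registry Species registry.
#' @param rt_tol Retention-time match tolerance in minutes (default 0.5).
#' @return A `response_factors` tibble: `species_id`, `factor`, `rt_min`,
#'   `channel` (`"sterol"` or `"adduct"`).
#' @export
calibrate_response <- function(standard_scans,
                               registry = build_default_registry(),
                               rt_tol = 0.5) {
  sterol_ids <- c("Chl", "CE 18:1", "CE 24:1")
  frag <- registry_channel(registry, "Chl", "M-H2O+H")
  pk <- detect_and_integrate(extract_eic(standard_scans, frag))
  area_at <- function(pk, rt) {
    hit <- pk[abs(pk$rt_apex - rt) <= rt_tol, ]
    if (nrow(hit) == 0) return(NA_real_)
    hit$area[which.max(hit$area)]
  }
  rts <- vapply(sterol_ids, function(id) {
    registry$rt_min[match(id, registry$id)]
  }, numeric(1))
  areas <- vapply(rts, function(rt) area_at(pk, rt), numeric(1))
  if (is.na(areas[1]) || areas[1] <= 0) {
    stop("no cholesterol peak found in the standard run", call. = FALSE)
  }
  out <- tibble::tibble(
    species_id = sterol_ids,
    factor = unname(areas / areas[1]),
    rt_min = unname(rts),
    channel = "sterol"
  )
  for (id in c("TAG 54:3", "WE 42:1")) {
    ch <- registry_channel(registry, id, "M+H")
    pk_a <- detect_and_integrate(extract_eic(standard_scans, ch))
    a <- area_at(pk_a, ch$rt_min)
    if (!is.na(a)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        species_id = id, factor = unname(a / areas[1]), rt_min = ch$rt_min,
        channel = "adduct"
      ))
    }
  }
  out
}

# Response factor for a sterol-channel peak at a given retention time:
# linear interpolation/extrapolation between the two CE calibration
# standards (response and retention are both linear in the ester's
# equivalent carbon number, so response is linear in retention time);
# cholesterol itself is 1 by definition.
sterol_factor_at_rt <- function(factors, rt) {
  st <- factors[factors$channel == "sterol" & factors$species_id != "Chl", ]
  if (nrow(st) < 2) {
    return(rep(if (nrow(st) == 1) st$factor else 1, length(rt)))
  }
  slope <- (st$factor[2] - st$factor[1]) / (st$rt_min[2] - st$rt_min[1])
  st$factor[1] + slope * (rt - st$rt_min[1])
}

#' Cholesterol share of the total sterol pool
#'
#' `100 x Chl / (Chl + sum of CE)` in molar-equivalent units: each
#' sterol-channel peak area is divided by its relative response factor
#' (cholesterol 1.00; CE interpolated along retention time between the
#' calibrated standards). CE peaks below the quantitation limit
#' (`snr < lloq_snr`) contribute nothing.
#'
#' @param peaks Assigned peak table from [pick_sample_peaks()].
#' @param factors [calibrate_response()] output; `NULL` treats all
#'   responses as 1.
#' @param lloq_snr Lower limit of quantitation as S/N (default 10).
#' @return Percentage in `[0, 100]`.
#' @export
chl_ce_ratio <- function(peaks, factors = NULL, lloq_snr = 10) {
  frag <- peaks[peaks$adduct == "M-H2O+H", ]
  chl <- frag[frag$label == "Chl", ]
  ce <- frag[!is.na(frag$label_id) & frag$snr >= lloq_snr, ]
  chl_molar <- sum(chl$area)
  ce_molar <- if (nrow(ce) == 0) 0 else {
    f <- if (is.null(factors)) rep(1, nrow(ce)) else
      sterol_factor_at_rt(factors, ce$rt_apex)
    sum(ce$area / f)
  }
  total <- chl_molar + ce_molar
  if (total <= 0) {
    stop("no sterol-channel signal; cannot form a Chl/CE ratio",
         call. = FALSE)
  }
  100 * chl_molar / total
}

#' CE chain-length profile
#'
#' Normalized percentage of cholesteryl-ester signal per grouped chain
#' label (saturated Cn:0 grouped with co-eluting monounsaturated
#' C(n+2):1; the `"unidentified"` bucket collects everything else), from
#' either the proton-adduct channels (`mode = "adduct"`) or the shared
#' m/z 369.35 fragment channel (`mode = "fragment"`). When response
#' factors are supplied, fragment-channel areas are converted to molar
#' equivalents before normalization.
#'
#' @param peaks Assigned peak table from [pick_sample_peaks()].
#' @param mode `"adduct"` or `"fragment"`.
#' @param factors Optional [calibrate_response()] output (fragment mode).
#' @return Tibble `label`, `label_id`, `percent`; percentages sum to 100.
#' @export
chain_profile <- function(peaks, mode = c("adduct", "fragment"),
                          factors = NULL) {
  mode <- match.arg(mode)
  want <- if (mode == "adduct") "M+H" else "M-H2O+H"
  ce <- peaks[peaks$adduct == want & !is.na(peaks$label_id), ]
  if (nrow(ce) == 0) {
    return(tibble::tibble(label = character(0), label_id = integer(0),
                          percent = numeric(0)))
  }
  value <- ce$area
  if (!is.null(factors) && mode == "fragment") {
    value <- value / sterol_factor_at_rt(factors, ce$rt_apex)
  }
  prof <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(label = ce$label,
                                   label_id = ce$label_id, value = value),
                    .data$label, .data$label_id),
    value = sum(.data$value), .groups = "drop"
  )
  prof$percent <- 100 * prof$value / sum(prof$value)
  dplyr::arrange(prof[, c("label", "label_id", "percent")], .data$label_id)
}

#' Apparent lipid class balance
#'
#' Normalized percentage of the four major meibum lipid classes. The
#' sterol classes are measured on the m/z 369.35 fragment channel in molar
#' equivalents (response-corrected where factors are known); WE and TAG are
#' proton-adduct areas corrected by their calibrated factors when
#' available, raw otherwise — hence an *apparent* balance.
#'
#' @param peaks Assigned peak table from [pick_sample_peaks()].
#' @param factors Optional [calibrate_response()] output.
#' @return Tibble `lipid_class`, `percent` over Chl, CE, WE, TAG; the
#'   percentages sum to 100.
#' @export
class_balance <- function(peaks, factors = NULL) {
  frag <- peaks[peaks$adduct == "M-H2O+H", ]
  chl <- sum(frag$area[frag$label == "Chl"])
  ce_pk <- frag[!is.na(frag$label_id), ]
  ce <- if (nrow(ce_pk) == 0) 0 else {
    f <- if (is.null(factors)) rep(1, nrow(ce_pk)) else
      sterol_factor_at_rt(factors, ce_pk$rt_apex)
    sum(ce_pk$area / f)
  }
  adduct_class_sum <- function(cls) {
    pk <- peaks[peaks$adduct == "M+H" & peaks$lipid_class == cls, ]
    if (nrow(pk) == 0) return(0)
    f <- rep(1, nrow(pk))
    if (!is.null(factors)) {
      idx <- match(pk$label, factors$species_id)
      f[!is.na(idx)] <- factors$factor[idx[!is.na(idx)]]
    }
    sum(pk$area / f)
  }
  vals <- c(Chl = chl, CE = ce,
            WE = adduct_class_sum("WE"), TAG = adduct_class_sum("TAG"))
  if (sum(vals) <= 0) {
    stop("no class signal at all; cannot form a balance", call. = FALSE)
  }
  tibble::tibble(lipid_class = names(vals),
                 percent = 100 * unname(vals) / sum(vals))
}

#' Quantify one sample end to end
#'
#' Convenience wrapper chaining [pick_sample_peaks()], [chl_ce_ratio()],
#' [chain_profile()] and [class_balance()] into a single per-sample report.
#'
#' @param scans A [scan_set()].
#' @param registry Species registry.
#' @param factors Optional [calibrate_response()] output.
#' @param lloq_snr Quantitation S/N limit (default 10).
#' @param min_snr Detection S/N threshold (default 5).
#' @param genotype,replicate Optional sample annotations.
#' @return A `quant_report` object: fields `peaks`, `chl_ce_ratio_percent`,
#'   `chain_profile_adduct`, `chain_profile_fragment`, `class_balance`,
#'   `genotype`, `replicate`.
#' @export
quantify_sample <- function(scans, registry = build_default_registry(),
                            factors = NULL, lloq_snr = 10, min_snr = 5,
                            genotype = NA_character_,
                            replicate = NA_integer_) {
  peaks <- pick_sample_peaks(scans, registry, min_snr = min_snr)
  structure(list(
    peaks = peaks,
    chl_ce_ratio_percent = chl_ce_ratio(peaks, factors, lloq_snr),
    chain_profile_adduct = chain_profile(peaks, "adduct"),
    chain_profile_fragment = chain_profile(peaks, "fragment", factors),
    class_balance = class_balance(peaks, factors),
    genotype = genotype,
    replicate = replicate
  ), class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("<quant_report> genotype %s, replicate %s\n",
              x$genotype, x$replicate))
  cat(sprintf("  %d assigned peaks; Chl share of sterols: %.2f%%\n",
              nrow(x$peaks), x$chl_ce_ratio_percent))
  cat("  class balance:",
      paste(sprintf("%s %.1f%%", x$class_balance$lipid_class,
                    x$class_balance$percent), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a quantitation report
#'
#' @param x A `quant_report`.
#' @param ... Unused.
#' @return Tibble, one row per sample x reported quantity (`metric`,
#'   `label`, `value`), suitable for binding across samples.
#' @export
#' @exportS3Method generics::tidy
tidy.quant_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(metric = "chl_ce_ratio_percent", label = "Chl",
                   value = x$chl_ce_ratio_percent),
    tibble::tibble(metric = "chain_profile_adduct",
                   label = x$chain_profile_adduct$label,
                   value = x$chain_profile_adduct$percent),
    tibble::tibble(metric = "chain_profile_fragment",
                   label = x$chain_profile_fragment$label,
                   value = x$chain_profile_fragment$percent),
    tibble::tibble(metric = "class_balance",
                   label = x$class_balance$lipid_class,
                   value = x$class_balance$percent)
  ) |>
    dplyr::mutate(genotype = x$genotype, replicate = x$replicate,
                  .before = 1)
}

#' Compare a quantity across genotype groups
#'
#' Per-group mean and standard deviation plus pairwise two-sided Welch
#' t-tests (no multiplicity correction; comparisons are reported pairwise).
#'
#' @param data Data frame with a grouping column and a value column.
#' @param group,value Column names (strings) of group and value.
#' @return List with `summary` (tibble: group, n, mean, sd) and
#'   `comparisons` (tibble: group1, group2, t, p_value).
#' @export
compare_groups <- function(data, group = "genotype", value = "value") {
  g <- factor(data[[group]])
  v <- data[[value]]
  counts <- table(g)
  if (any(counts < 2)) {
    stop("every group needs at least 2 replicates", call. = FALSE)
  }
  summ <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = g, value = v), .data$group),
    n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
    .groups = "drop"
  )
  lv <- levels(g)
  comps <- NULL
  if (length(lv) >= 2) {
    pairs <- utils::combn(lv, 2)
    comps <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- v[g == pairs[1, i]]
      b <- v[g == pairs[2, i]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
        return(tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                              t = 0, p_value = 1))
      }
      tt <- stats::t.test(a, b)
      tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                     t = unname(tt$statistic), p_value = tt$p.value)
    })
  }
  list(summary = summ, comparisons = comps)
}

#' Summarize quantitation reports across genotypes
#'
#' Pools tidied [quantify_sample()] reports and produces per-genotype means
#' and standard deviations for every reported quantity, plus pairwise Welch
#' comparisons of the cholesterol-to-sterol ratio when at least two
#' genotypes with two replicates each are present.
#'
#' @param reports List of `quant_report` objects.
#' @return List with `table` (tidy per-metric summary) and `ratio_tests`
#'   (pairwise comparisons of the sterol ratio, or `NULL`).
#' @export
genotype_summary <- function(reports) {
  if (length(reports) == 0) stop("no reports supplied", call. = FALSE)
  tidy_all <- purrr::map_dfr(reports, tidy)
  tab <- dplyr::summarise(
    dplyr::group_by(tidy_all, .data$genotype, .data$metric, .data$label),
    n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
    .groups = "drop"
  )
  ratios <- tidy_all[tidy_all$metric == "chl_ce_ratio_percent", ]
  tests <- NULL
  counts <- table(ratios$genotype)
  if (length(counts) >= 2 && all(counts >= 2)) {
    tests <- compare_groups(ratios, "genotype", "value")$comparisons
  }
  list(table = tab, ratio_tests = tests)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
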