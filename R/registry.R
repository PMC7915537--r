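#' Build the default meibum lipid species registry
#'
#' Constructs the channel table used for EIC extraction and peak assignment:
#' one row per (species, ion channel). The species set covers free
#' cholesterol (Chl), saturated and monounsaturated cholesteryl esters (CE)
#' with fatty-acid chains C10 to C34, the six major monitored wax esters
#' (WE), two triacylglycerols (TAG, including triolein), and one
#' cholesteryl (O)-acyl-omega-hydroxy fatty acid (Chl-OAHFA). Every
#' cholesterol-containing species carries, besides its proton adduct, the
#' common sterol fragment channel at m/z 369.3521 (dehydrated protonated
#' cholesterol, C27H45+), which lets all sterol lipids be detected and
#' quantified on a single channel.
#'
#' Retention times for CE follow a linear model in equivalent carbon number
#' (ECN = fatty-acid carbons - 2 x double bonds) anchored at the measured
#' standards cholesteryl oleate (18:1, 21.03 min) and cholesteryl nervonate
#' (24:1, 28.48 min); free cholesterol elutes at 6.93 min. Saturated Cn:0
#' and monounsaturated C(n+2):1 esters share an ECN and therefore co-elute,
#' which is why they are reported as grouped labels.
#'
#' @param window_mda EIC window width in millidalton (total width; the
#'   match window is +/- `window_mda / 2`). Default 50.
#' @return A tibble of class `lipid_registry` with columns `id`,
#'   `lipid_class`, `fa_carbons`, `fa_db`, `neutral_formula`, `adduct`,
#'   `target_mz`, `window_mda`, `rt_min`.
#' @examples
#' reg <- build_default_registry()
#' dplyr::filter(reg, id == "Chl")
#' @export
build_default_registry <- function(window_mda = 50) {
  stopifnot(window_mda > 0)

  ce_rt_slope <- (28.48 - 21.03) / 6 # min per ECN unit, from CO/CN standards
  ce_rt_intercept <- 21.03 - 16 * ce_rt_slope
  ce_rt <- function(n, d) ce_rt_intercept + ce_rt_slope * (n - 2 * d)

  species <- list(
    tibble::tibble(
      id = "Chl", lipid_class = "Chl",
      fa_carbons = NA_integer_, fa_db = NA_integer_,
      neutral_formula = "C27H46O", rt_min = 6.93
    )
  )

  ce_grid <- expand.grid(n = 10:34, d = 0:1)
  species <- c(species, list(tibble::tibble(
    id = sprintf("CE %d:%d", ce_grid$n, ce_grid$d),
    lipid_class = "CE",
    fa_carbons = as.integer(ce_grid$n),
    fa_db = as.integer(ce_grid$d),
    neutral_formula = ce_formula(ce_grid$n, ce_grid$d),
    rt_min = ce_rt(ce_grid$n, ce_grid$d)
  )))

  # six monitored WE; lignoceryl oleate (42:1) anchored at 22.35 min
  we <- tibble::tribble(
    ~n, ~d,
    42L, 1L,
    43L, 1L,
    44L, 1L,
    46L, 1L,
    48L, 2L,
    50L, 2L
  )
  species <- c(species, list(tibble::tibble(
    id = sprintf("WE %d:%d", we$n, we$d),
    lipid_class = "WE",
    fa_carbons = we$n, fa_db = we$d,
    neutral_formula = we_formula(we$n, we$d),
    rt_min = 22.35 + 0.62 * (we$n - 42) - 1.24 * (we$d - 1)
  )))

  species <- c(species, list(tibble::tibble(
    id = c("TAG 52:3", "TAG 54:3"),
    lipid_class = "TAG",
    fa_carbons = c(52L, 54L), fa_db = c(3L, 3L),
    neutral_formula = c(tag_formula(52, 3), tag_formula(54, 3)),
    rt_min = c(17.40, 18.64) # TAG 54:3 is triolein (18.64 min standard)
  )))

  species <- c(species, list(tibble::tibble(
    id = "Chl-OAHFA 50:2", lipid_class = "Chl-OAHFA",
    fa_carbons = 50L, fa_db = 2L,
    neutral_formula = "C75H134O4", # (M+H)+ = C75H135O4+
    rt_min = 44.5 # elutes after the last CE on the shared fragment channel
  )))

  species <- dplyr::bind_rows(species)

  one_channel <- function(row, adduct) {
    tibble::tibble(
      id = row$id, lipid_class = row$lipid_class,
      fa_carbons = row$fa_carbons, fa_db = row$fa_db,
      neutral_formula = row$neutral_formula,
      adduct = adduct,
      target_mz = adduct_mz(
        list(neutral_formula = row$neutral_formula,
             lipid_class = row$lipid_class,
             fa_carbons = row$fa_carbons,
             fa_double_bonds = row$fa_db),
        adduct
      ),
      window_mda = window_mda,
      rt_min = row$rt_min
    )
  }

  channels <- purrr::map_dfr(seq_len(nrow(species)), function(i) {
    row <- species[i, ]
    adducts <- switch(row$lipid_class,
      "Chl" = c("M+H", "M-H2O+H"),
      "CE" = c("M+H", "M-H2O+H"),
      "Chl-OAHFA" = c("M+H", "M-H2O+H"),
      "M+H"
    )
    purrr::map_dfr(adducts, function(a) one_channel(row, a))
  })

  structure(channels, class = c("lipid_registry", class(channels)))
}

#' Look up a single channel in a registry
#'
#' @param registry A `lipid_registry` tibble.
#' @param species_id Species identifier, e.g. `"CE 28:1"`.
#' @param adduct Channel adduct, e.g. `"M+H"` or `"M-H2O+H"`.
#' @return One registry row.
#' @export
registry_channel <- function(registry, species_id, adduct) {
  hit <- registry[registry$id == species_id & registry$adduct == adduct, ]
  if (nrow(hit) != 1L) {
    stop("no unique channel for ", species_id, " / ", adduct, call. = FALSE)
  }
  hit
}

# Grouped reporting labels for CE chain profiles: saturated Cn:0 esters are
# grouped with the co-eluting monounsaturated C(n+2):1 esters. Label 21 is
# the unidentified bucket.
ce_label_table <- function() {
  tibble::tribble(
    ~label_id, ~fa_carbons, ~fa_db,
    1L, 10L, 0L,
    2L, 12L, 0L, 2L, 14L, 1L,
    3L, 14L, 0L, 3L, 16L, 1L,
    4L, 15L, 0L,
    5L, 16L, 0L, 5L, 18L, 1L,
    6L, 17L, 0L,
    7L, 18L, 0L, 7L, 20L, 1L,
    8L, 19L, 0L,
    9L, 20L, 0L, 9L, 22L, 1L,
    10L, 21L, 0L,
    11L, 22L, 0L, 11L, 24L, 1L,
    12L, 23L, 0L,
    13L, 24L, 0L, 13L, 26L, 1L,
    14L, 25L, 0L,
    15L, 26L, 0L, 15L, 28L, 1L,
    16L, 27L, 0L,
    17L, 28L, 0L, 17L, 30L, 1L,
    18L, 29L, 0L,
    19L, 30L, 0L, 19L, 32L, 1L,
    20L, 34L, 1L
  )
}

ce_label_string <- function(label_id) {
  tab <- ce_label_table()
  members <- tab[tab$label_id == label_id, ]
  paste0(paste(sprintf("C%d:%d", members$fa_carbons, members$fa_db),
               collapse = "/"), "-CE")
}

#' Build the peak assignment table
#'
#' Maps (m/z, retention time) observations to species labels. Proton-adduct
#' channels have unique masses, so they match on m/z alone; the shared
#' sterol fragment channel at m/z 369.35 is disambiguated by retention time
#' (cholesterol at 6.93 min, each CE at its ECN-predicted time, Chl-OAHFA
#' late). CE entries carry the grouped chain labels used for reporting
#' (grouping co-eluting Cn:0 / C(n+2):1 pairs); CE species outside the
#' grouped label set fall into the `"unidentified"` bucket.
#'
#' @param registry A `lipid_registry` tibble.
#' @param mz_tol m/z match tolerance in Da (default 0.025, half the 50 mDa
#'   EIC window).
#' @param rt_tol Retention-time half-window in minutes for RT-restricted
#'   entries (default 0.5).
#' @return Tibble with columns `label`, `label_id`, `species_id`, `adduct`,
#'   `mz`, `mz_tol`, `rt_lo`, `rt_hi` (NA bounds = unrestricted).
#' @export
build_assignment_table <- function(registry, mz_tol = 0.025, rt_tol = 0.5) {
  lab_tab <- ce_label_table()
  label_of <- function(class, n, d, id) {
    if (class != "CE") {
      return(list(label = id, label_id = NA_integer_))
    }
    hit <- lab_tab[lab_tab$fa_carbons == n & lab_tab$fa_db == d, ]
    if (nrow(hit) == 0) {
      return(list(label = "unidentified", label_id = 21L))
    }
    list(label = ce_label_string(hit$label_id), label_id = hit$label_id)
  }

  tab <- purrr::map_dfr(seq_len(nrow(registry)), function(i) {
    ch <- registry[i, ]
    lab <- label_of(ch$lipid_class, ch$fa_carbons, ch$fa_db, ch$id)
    # the fragment channel is shared by all sterols: restrict by RT there;
    # adduct channels are mass-unique and match on m/z alone
    restricted <- ch$adduct == "M-H2O+H"
    tibble::tibble(
      label = if (ch$id == "Chl") "Chl" else lab$label,
      label_id = if (ch$id == "Chl") NA_integer_ else lab$label_id,
      species_id = ch$id,
      adduct = ch$adduct,
      mz = ch$target_mz,
      mz_tol = mz_tol,
      rt_lo = if (restricted) ch$rt_min - rt_tol else NA_real_,
      rt_hi = if (restricted) ch$rt_min + rt_tol else NA_real_
    )
  })
  # labeled entries win exact m/z+RT ties against the unidentified bucket;
  # fully co-eluting duplicates on the shared fragment channel (same m/z,
  # same RT window) are collapsed so entries never overlap
  tab <- tab[order(tab$label == "unidentified"), ]
  key <- paste(round(tab$mz, 4), tab$rt_lo, tab$rt_hi)
  tab[!(duplicated(key) & !is.na(tab$rt_lo)), ]
}

#' Assign an observed peak to a species label
#'
#' Finds the assignment-table entry closest in m/z among those whose m/z
#' tolerance and (where present) retention-time window cover the
#' observation. Returns `"unidentified"` when nothing matches.
#'
#' @param mz Observed m/z (Da).
#' @param rt Observed retention time (minutes).
#' @param table Assignment table from [build_assignment_table()].
#' @return A species label string.
#' @examples
#' tab <- build_assignment_table(build_default_registry())
#' assign_peak(369.3521, 6.93, tab) # "Chl"
#' @export
assign_peak <- function(mz, rt, table) {
  ok <- abs(table$mz - mz) <= table$mz_tol &
    (is.na(table$rt_lo) | (rt >= table$rt_lo & rt <= table$rt_hi))
  hits <- table[ok, ]
  if (nrow(hits) == 0) {
    return("unidentified")
  }
  hits$label[which.min(abs(hits$mz - mz))]
}
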