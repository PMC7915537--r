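# Monoisotopic atomic masses (IUPAC). 12C is exact by definition.
MONOISOTOPIC_MASS <- c(
  C  = 12,
  H  = 1.00782503207,
  O  = 15.9949146196,
  N  = 14.0030740048,
  Na = 22.9897692809,
  K  = 38.96370668
)

PROTON_MASS <- MONOISOTOPIC_MASS[["H"]]
WATER_MASS  <- 2 * MONOISOTOPIC_MASS[["H"]] + MONOISOTOPIC_MASS[["O"]]

#' Parse an elemental formula string
#'
#' Converts a Hill-style formula such as `"C27H46O"` into a named integer
#' vector of element counts. Only elements with known monoisotopic masses
#' (C, H, O, N, Na, K) are accepted. The empty string is a valid formula
#' with no atoms.
#'
#' @param formula A single formula string, e.g. `"C55H99O2"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C27H46O")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (formula == "") {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  ns <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(ns == "", 1L, suppressWarnings(as.integer(ns)))
  unknown <- setdiff(syms, names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- tapply(counts, syms, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of an elemental formula
#'
#' Sums monoisotopic atomic masses over the formula. The electron mass is
#' deliberately *not* subtracted for cations: m/z values are reported as
#' plain formula sums, the convention used throughout meibum APCI-MS work
#' (the dehydrated protonated cholesterol fragment C27H45+ is quoted as
#' 369.3521, the neutral-formula sum).
#'
#' @param formula Formula string or named count vector from
#'   [parse_formula()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C27H45") # 369.3521, the common sterol fragment
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0) {
    return(0)
  }
  stopifnot(all(counts >= 0))
  unknown <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(MONOISOTOPIC_MASS[names(counts)] * counts)
}

# Mass shifts for supported adduct / fragment channels. "M-FA+H" depends on
# the FA moiety and is handled separately.
ADDUCT_SHIFTS <- c(
  "M+H"      = 1.00782503207,
  "M-H2O+H"  = 1.00782503207 - (2 * 1.00782503207 + 15.9949146196),
  "M+NH4"    = 14.0030740048 + 4 * 1.00782503207,
  "M+Na"     = 22.9897692809,
  "M+K"      = 38.96370668
)

#' m/z of an adduct or fragment ion for a lipid species
#'
#' Applies an adduct mass shift to the species' neutral monoisotopic mass.
#' The sterol fragment channel (`"M-H2O+H"`, yielding C27H45+ at m/z
#' 369.3521 for all cholesterol-containing lipids) is only valid for
#' sterol classes (Chl, CE, Chl-OAHFA). `"M-FA+H"` (neutral loss of the
#' fatty acid, used for CE and TAG) requires the species to carry a fatty
#' acid moiety.
#'
#' @param species One row of a species registry (see
#'   [build_default_registry()]), or a list with `neutral_formula`,
#'   `lipid_class`, `fa_carbons`, `fa_double_bonds`.
#' @param adduct One of `"M+H"`, `"M-H2O+H"`, `"M-FA+H"`, `"M+NH4"`,
#'   `"M+Na"`, `"M+K"`.
#' @return m/z in Da.
#' @export
adduct_mz <- function(species, adduct) {
  if (is.data.frame(species)) {
    stopifnot(nrow(species) == 1L)
    species <- as.list(species)
  }
  neutral <- monoisotopic_mass(species$neutral_formula)
  sterol_classes <- c("Chl", "CE", "Chl-OAHFA")
  if (adduct == "M-H2O+H") {
    if (!(species$lipid_class %in% sterol_classes)) {
      stop("sterol fragment channel requested for non-sterol class '",
           species$lipid_class, "'", call. = FALSE)
    }
    if (species$lipid_class == "Chl") {
      return(neutral - WATER_MASS + PROTON_MASS)
    }
    # esterified sterols lose the acyl moiety instead of water and yield
    # the identical C27H45+ ion
    return(monoisotopic_mass("C27H45"))
  }
  if (adduct == "M-FA+H") {
    if (is.null(species$fa_carbons) || is.na(species$fa_carbons)) {
      stop("'M-FA+H' requires a fatty-acid moiety", call. = FALSE)
    }
    return(neutral - fa_mass(species$fa_carbons, species$fa_double_bonds) +
             PROTON_MASS)
  }
  if (!adduct %in% names(ADDUCT_SHIFTS)) {
    stop("unsupported adduct: ", adduct, call. = FALSE)
  }
  neutral + ADDUCT_SHIFTS[[adduct]]
}

# Monoisotopic mass of a free fatty acid CnH(2n-2d)O2.
fa_mass <- function(carbons, double_bonds) {
  stopifnot(carbons > 0, double_bonds >= 0)
  monoisotopic_mass(stats::setNames(
    as.integer(c(carbons, 2 * carbons - 2 * double_bonds, 2)),
    c("C", "H", "O")
  ))
}

# Neutral elemental formula strings for the lipid classes handled here.
# CE: cholesterol (C27H46O) + FA - H2O -> C(27+n) H(44+2n-2d) O2
# WE: fatty alcohol + FA, total carbons n, double bonds d -> Cn H(2n-2d) O2
# TAG: glycerol + 3 FA - 3 H2O, FA carbons n, double bonds d
#      -> C(n+3) H(2n+2-2d) O6
ce_formula <- function(n, d) sprintf("C%dH%dO2", 27 + n, 44 + 2 * n - 2 * d)
we_formula <- function(n, d) sprintf("C%dH%dO2", n, 2 * n - 2 * d)
tag_formula <- function(n, d) sprintf("C%dH%dO6", n + 3, 2 * n + 2 - 2 * d)
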