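#' Wild-type load from total and mutant plate counts
#'
#' In a two-strain competition the WT load is the total count on the
#' antibiotic-free plate minus the mutant count on the selective plate.
#' A mutant count exceeding the total is a counting inconsistency and is an
#' error, never silently clamped.
#'
#' @param cfu_total,cfu_mutant cfu per g (non-negative; vectorized).
#' @return numeric: `cfu_total - cfu_mutant` (zero allowed).
#' @export
wt_from_total <- function(cfu_total, cfu_mutant) {
  if (any(cfu_total < 0) || any(cfu_mutant < 0)) {
    stop("cfu counts must be non-negative", call. = FALSE)
  }
  if (any(cfu_mutant > cfu_total)) {
    stop("cfu_mutant exceeds cfu_total: counting inconsistency", call. = FALSE)
  }
  cfu_total - cfu_mutant
}

#' Normalized competitive index
#'
#' `(cfu_mutant / cfu_wt) / (inoc_mutant_frac / inoc_wt_frac)`; 1 is the
#' fitness-neutral expectation. A zero mutant count gives C.I 0 flagged
#' `below_detection` (a pseudocount mode is available); a zero WT count is
#' undefined and gives `NA` flagged `undefined`.
#'
#' @param cfu_mutant,cfu_wt output counts (cfu per g; vectorized).
#' @param inoc_mutant_frac,inoc_wt_frac inoculum fractions (> 0).
#' @param pseudocount optional count added to both strains before the
#'   ratio (default 0, i.e. off).
#' @return numeric C.I values with a character attribute `"flags"`
#'   (`""`, `"below_detection"` or `"undefined"` per element).
#' @export
normalized_ci <- function(cfu_mutant, cfu_wt, inoc_mutant_frac,
                          inoc_wt_frac, pseudocount = 0) {
  if (any(inoc_mutant_frac <= 0) || any(inoc_wt_frac <= 0)) {
    stop("inoculum fractions must be positive", call. = FALSE)
  }
  if (any(cfu_mutant < 0) || any(cfu_wt < 0)) {
    stop("cfu counts must be non-negative", call. = FALSE)
  }
  m <- cfu_mutant + pseudocount
  w <- cfu_wt + pseudocount
  inoc_ratio <- inoc_mutant_frac / inoc_wt_frac
  ci <- ifelse(w == 0, NA_real_, (m / w) / inoc_ratio)
  flags <- ifelse(w == 0, "undefined",
                  ifelse(m == 0, "below_detection", ""))
  ci[!is.na(ci) & m == 0] <- 0
  attr(ci, "flags") <- flags
  ci
}

#' Competitive indices for a plating table
#'
#' @param plating data frame with columns `cfu_total`, `cfu_mutant`,
#'   `inoc_mutant_frac`, `inoc_wt_frac` (e.g. from
#'   [generate_competition()]).
#' @param pseudocount see [normalized_ci()].
#' @return `plating` with `cfu_wt`, `ci` and `ci_flag` columns appended.
#' @export
compute_ci <- function(plating, pseudocount = 0) {
  wt <- wt_from_total(plating$cfu_total, plating$cfu_mutant)
  ci <- normalized_ci(plating$cfu_mutant, wt, plating$inoc_mutant_frac,
                      plating$inoc_wt_frac, pseudocount = pseudocount)
  plating$cfu_wt <- wt
  plating$ci <- as.numeric(ci)
  plating$ci_flag <- attr(ci, "flags")
  plating
}

#' Absolute load of a barcoded strain
#'
#' The barcode's relative density (from real-time PCR) times the cfu
#' recovered from selective plating.
#'
#' @param rel_density fraction in `[0, 1]` (vectorized).
#' @param cfu_plate cfu per g from selective plating (>= 0).
#' @return numeric cfu per g for the barcode.
#' @export
barcode_load <- function(rel_density, cfu_plate) {
  if (any(rel_density < 0) || any(cfu_plate < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  if (any(rel_density > 1)) {
    stop("rel_density must not exceed 1", call. = FALSE)
  }
  rel_density * cfu_plate
}

#' Density-normalized reporter signal
#'
#' Subtracts the autofluorescence control and normalizes to bacterial
#' density: `(fluorescence - autofluorescence) / od`. Negative corrected
#' signals are floored at 0 and flagged.
#'
#' @param fluorescence reporter signal, arbitrary units (vectorized).
#' @param od optical density (uOD600, > 0).
#' @param autofluorescence matched non-reporter control signal.
#' @return numeric MFI per uOD600 with attribute `"flags"` (`""` or
#'   `"floored"`).
#' @export
reporter_normalize <- function(fluorescence, od, autofluorescence) {
  if (any(od <= 0)) stop("od must be positive", call. = FALSE)
  v <- (fluorescence - autofluorescence) / od
  flags <- ifelse(v < 0, "floored", "")
  v[v < 0] <- 0
  attr(v, "flags") <- flags
  v
}

#' Compare competitive indices between two groups
#'
#' Two-tailed Mann-Whitney U test on C.I values with the significance band
#' convention of competition figure legends.
#'
#' @param ci_a,ci_b numeric C.I vectors (non-empty).
#' @return list with `statistic` (U), `p.value`, `band`, and group medians
#'   `median_a`, `median_b` (medians, not means, summarize C.I groups).
#' @export
compare_ci_groups <- function(ci_a, ci_b) {
  mw <- mann_whitney_u(ci_a, ci_b)
  list(statistic = mw$statistic, p.value = mw$p.value,
       band = significance_band(mw$p.value),
       median_a = median(ci_a), median_b = median(ci_b))
}
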