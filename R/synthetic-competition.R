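#' Configuration of a simulated competition experiment
#'
#' Describes pairwise mutant-versus-wild-type plating competitions in a set
#' of subjects: each mutant strain has a true competitive index (the factor
#' by which its output ratio against the WT deviates from the inoculum
#' ratio) and the observed counts carry multiplicative log-normal noise of
#' mean 1 with the given coefficient of variation.
#'
#' @param seed integer RNG seed.
#' @param n_subjects number of subjects (mice).
#' @param timepoints integer vector of sampling days.
#' @param true_ci named positive numeric vector: true competitive index per
#'   mutant strain.
#' @param inoculum_fractions named fractions of the inoculum, one entry per
#'   mutant strain plus `"WT"`; must sum to 1 (tolerance 1e-9).
#' @param total_load expected cfu per g of the full community.
#' @param noise_cv coefficient of variation of the log-normal count noise.
#' @return an object of class `competition_config`.
#' @export
competition_config <- function(seed, n_subjects, timepoints = c(1L, 3L),
                               true_ci, inoculum_fractions,
                               total_load = 1e8, noise_cv = 0) {
  if (any(true_ci <= 0)) stop("true_ci must be positive", call. = FALSE)
  if (is.null(names(true_ci)) || is.null(names(inoculum_fractions))) {
    stop("true_ci and inoculum_fractions must be named", call. = FALSE)
  }
  if (!"WT" %in% names(inoculum_fractions)) {
    stop("inoculum_fractions must include 'WT'", call. = FALSE)
  }
  if (!setequal(names(true_ci), setdiff(names(inoculum_fractions), "WT"))) {
    stop("strain names in true_ci and inoculum_fractions disagree", call. = FALSE)
  }
  if (abs(sum(inoculum_fractions) - 1) > 1e-9) {
    stop("inoculum fractions must sum to 1", call. = FALSE)
  }
  if (any(inoculum_fractions <= 0)) {
    stop("inoculum fractions must be positive", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 timepoints = as.integer(timepoints), true_ci = true_ci,
                 inoculum_fractions = inoculum_fractions,
                 total_load = total_load, noise_cv = noise_cv),
            class = "competition_config")
}

# log-normal factor with mean exactly 1 at the requested CV
lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate plating observations from pairwise competitions
#'
#' For every subject, day and mutant strain, simulates the selective-plating
#' observation of that mutant against the WT: the output mutant/WT ratio is
#' `true_ci * inoculum_ratio` perturbed by mean-1 log-normal noise, and
#' `cfu_total` is the mutant + WT pair load. With `noise_cv = 0` the
#' competitive index recomputed from the table equals `true_ci` exactly.
#'
#' @param config a [competition_config()].
#' @return a data frame with columns `subject_id`, `day`, `strain`,
#'   `cfu_total`, `cfu_mutant`, `inoc_mutant_frac`, `inoc_wt_frac`,
#'   `true_ci`.
#' @export
generate_competition <- function(config) {
  stopifnot(inherits(config, "competition_config"))
  with_seed(config$seed, {
    strains <- names(config$true_ci)
    fw <- config$inoculum_fractions[["WT"]]
    rows <- expand.grid(strain = strains, day = config$timepoints,
                        subject_id = sprintf("m%02d", seq_len(config$n_subjects)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[order(rows$subject_id, rows$day, rows$strain), , drop = FALSE]
    n <- nrow(rows)
    fm <- config$inoculum_fractions[rows$strain]
    ratio <- config$true_ci[rows$strain] * (fm / fw) * lnorm_factor(n, config$noise_cv)
    pair_load <- config$total_load * (fm + fw) * lnorm_factor(n, config$noise_cv)
    cfu_mutant <- pair_load * ratio / (1 + ratio)
    out <- data.frame(subject_id = rows$subject_id, day = rows$day,
                      strain = rows$strain, cfu_total = pair_load,
                      cfu_mutant = cfu_mutant,
                      inoc_mutant_frac = unname(fm), inoc_wt_frac = fw,
                      true_ci = unname(config$true_ci[rows$strain]),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
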