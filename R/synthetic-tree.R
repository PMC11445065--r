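#' Generate a rooted binary tree over cohort genomes
#'
#' Produces a rooted, binary newick tree whose tips are the genome ids.
#' Either a random topology (via a seeded Yule-process tree) or, when
#' `group_by` is supplied, a topology in which the genomes sharing each
#' state form one clade (useful to construct monophyletic test cases).
#'
#' @param genome_ids character vector of tip labels (>= 3, unique), or a
#'   `sim_cohort` whose genome names are used.
#' @param seed integer RNG seed for the random topology.
#' @param group_by optional named character vector mapping genome id to a
#'   state; tips are grouped into one clade per state.
#' @return a newick string (rooted, binary).
#' @export
generate_tree <- function(genome_ids, seed = 1L, group_by = NULL) {
  if (inherits(genome_ids, "sim_cohort")) {
    genome_ids <- names(genome_ids$genomes)
  }
  if (length(genome_ids) < 3) stop("need at least 3 genomes", call. = FALSE)
  if (anyDuplicated(genome_ids)) {
    stop("duplicate genome ids", call. = FALSE)
  }
  ladder <- function(tips) {
    # right-laddered binary subtree over the given tips
    out <- tips[length(tips)]
    if (length(tips) > 1) {
      for (i in rev(seq_len(length(tips) - 1L))) {
        out <- paste0("(", tips[i], ",", out, ")")
      }
    }
    out
  }
  if (!is.null(group_by)) {
    miss <- setdiff(genome_ids, names(group_by))
    if (length(miss) > 0) {
      stop("group_by is missing genomes: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    states <- unique(group_by[genome_ids])
    clades <- vapply(states, function(s) {
      ladder(genome_ids[group_by[genome_ids] == s])
    }, "")
    nwk <- paste0(ladder(clades), ";")
    # a single state would give an unparenthesised ladder ending in ';'
    if (length(clades) == 1 && length(genome_ids) > 1) {
      nwk <- paste0(clades, ";")
    }
    return(nwk)
  }
  tr <- with_seed(seed, ape::rtree(length(genome_ids), rooted = TRUE,
                                   tip.label = sample(genome_ids)))
  ape::write.tree(tr)
}
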