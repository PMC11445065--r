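as_rooted_tree <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree)) {
    if (!requireNamespace("phangorn", quietly = TRUE)) {
      stop("unrooted input tree: midpoint rooting requires the phangorn ",
           "package", call. = FALSE)
    }
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' Fitch small-parsimony count of codon-state changes on a tree
#'
#' Counts the minimum number of character-state changes needed to explain
#' the tip states on the rooted tree (Fitch algorithm; polytomies are
#' resolved deterministically first, unrooted trees are midpoint-rooted —
#' the rooting choice affects monophyly statements and is applied
#' consistently).
#'
#' @param tree a `phylo` object or newick string.
#' @param tip_states named character vector mapping every tip label to a
#'   state (e.g. a codon class).
#' @return integer: minimum number of state changes (0 when all tips share
#'   one state).
#' @export
fitch_parsimony <- function(tree, tip_states) {
  tree <- as_rooted_tree(tree)
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss) > 0 || anyNA(tip_states[tree$tip.label])) {
    stop("unlabelled tip(s): ",
         paste(c(miss, tree$tip.label[is.na(tip_states[tree$tip.label])]),
               collapse = ", "), call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tip_states[[tree$tip.label[i]]]
  po <- ape::reorder.phylo(tree, "postorder")
  changes <- 0L
  parents <- unique(po$edge[, 1])
  for (p in parents) {
    kids <- po$edge[po$edge[, 1] == p, 2]
    acc <- sets[[kids[1]]]
    for (k in kids[-1]) {
      inter <- intersect(acc, sets[[k]])
      if (length(inter) > 0) {
        acc <- inter
      } else {
        acc <- union(acc, sets[[k]])
        changes <- changes + 1L
      }
    }
    sets[[p]] <- acc
  }
  changes
}

#' Is a codon state monophyletic on the tree?
#'
#' TRUE iff the tips carrying `state` form exactly one clade of the rooted
#' tree (a single tip counts as a trivial clade).
#'
#' @param tree a `phylo` object or newick string.
#' @param tip_states named character vector of tip states.
#' @param state the state to test; must be present in at least one tip.
#' @return logical.
#' @export
is_state_monophyletic <- function(tree, tip_states, state) {
  tree <- as_rooted_tree(tree)
  tips <- names(tip_states)[tip_states == state]
  tips <- intersect(tree$tip.label, tips)
  if (length(tips) == 0) {
    stop("state '", state, "' is absent from the tips", call. = FALSE)
  }
  if (length(tips) == 1) return(TRUE)
  ape::is.monophyletic(tree, tips)
}
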