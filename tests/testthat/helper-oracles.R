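# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# Brute-force affine-gap Smith-Waterman best score (full quadratic DP in R).
# Gap of length L costs go + L * ge; N never matches.
sw_oracle <- function(q, s, match = 2, mismatch = -3, go = -5, ge = -2) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  n <- length(qv)
  m <- length(sv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + go + ge, E[i, j - 1] + ge)
      F[i, j] <- max(H[i - 1, j] + go + ge, F[i - 1, j] + ge)
      sub <- if (qv[i - 1] == sv[j - 1] && qv[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# U statistic by direct pairwise win counting (not rank sums).
u_pairs <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Two-tailed p by complete enumeration of group assignments of the pooled
# sample, with U computed by pairwise counting.
mwu_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  obs <- u_pairs(x, y)
  combos <- combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_pairs(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Minimum state changes by exhaustive assignment of internal-node states.
fitch_exhaustive <- function(tree, tip_states) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tree <- ape::multi2di(tree, random = FALSE)
  states <- sort(unique(unname(tip_states)))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tip_vec <- unname(tip_states[tree$tip.label])
  grid <- do.call(expand.grid,
                  c(rep(list(states), nnode), stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- c(tip_vec, as.character(unlist(grid[r, ])))
    best <- min(best, sum(st[tree$edge[, 1]] != st[tree$edge[, 2]]))
  }
  best
}

# Hand-constructed flanked region for caller unit tests.
make_region <- function(sequence, hit_offset, qstart = 0L,
                        hit_length = NULL, strand = "+") {
  structure(list(sequence = sequence, window_start = 0L,
                 window_end = nchar(sequence), hit_offset = hit_offset,
                 left_flank = hit_offset,
                 right_flank = 0L, qstart = qstart,
                 hit_length = if (is.null(hit_length))
                   nchar(sequence) - hit_offset else hit_length,
                 source = list(genome_id = NA_character_,
                               contig_id = NA_character_, strand = strand)),
            class = "flanked_region")
}
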