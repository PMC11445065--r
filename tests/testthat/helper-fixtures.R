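# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Training cohort: one undiverged genome carrying 60 annotated genes with
# E. coli-like start-codon usage (48 ATG / 7 GTG / 5 TTG) and SD spacers
# spread over the model's bins.
fixture_training_cohort <- function() {
  memo("training_cohort", function() {
    codons <- rep(c("ATG", "GTG", "TTG"), c(48, 7, 5))
    spacers <- rep(c(5, 6, 7, 8, 9, 10, 13), length.out = 60)
    strands <- rep(c("+", "-"), length.out = 60)
    genes <- lapply(seq_len(60), function(i) {
      planted_gene(sprintf("tg%02d", i), orf_length = 210,
                   start_codon = codons[i], sd_spacer = spacers[i],
                   strand = strands[i])
    })
    generate_cohort(simulation_config(seed = 4242, n_genomes = 1,
                                      contig_length = 25000, genes = genes))
  })
}

fixture_model <- function() {
  memo("model", function() {
    coh <- fixture_training_cohort()
    train_start_model(coh$genomes[[1]], coh$annotation)
  })
}

# Small survey cohort: 12 genomes, one GTG regulator, 3% divergence.
fixture_survey_cohort <- function() {
  memo("survey", function() {
    generate_cohort(simulation_config(
      seed = 99, n_genomes = 12, contig_length = 2000,
      genes = list(planted_gene("lacI", orf_length = 300,
                                start_codon = "GTG")),
      divergence_rate = 0.03))
  })
}

# A scored-candidate table with chosen codons/scores/lengths, for
# resolve_starts unit tests.
make_scored <- function(codon, total_score, orf_length,
                        rbs_present = TRUE, pos = NULL) {
  n <- length(codon)
  data.frame(pos = pos %||% seq(0, by = 3, length.out = n), codon = codon,
             stop_pos = 300L, orf_length = orf_length,
             frame_anchor = 0L, rbs_score = total_score, rbs_present = rbs_present,
             start_score = 0, total_score = total_score,
             truncated = FALSE, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
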