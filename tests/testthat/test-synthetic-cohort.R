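codon_on_strand <- function(contig, pos, strand) {
  tri <- substr(contig, pos + 1, pos + 3)
  if (strand == "-") revcomp(tri) else tri
}

test_that("planted genes appear once at the recorded position with the recorded codon", {
  genes <- list(planted_gene("a", 120, "ATG", strand = "+"),
                planted_gene("b", 90, "GTG", strand = "-"),
                planted_gene("c", 150, "TTG", strand = "+"))
  coh <- generate_cohort(simulation_config(seed = 1, n_genomes = 3,
                                           contig_length = 3000,
                                           genes = genes,
                                           divergence_rate = 0.1))
  man <- coh$manifest
  expect_equal(nrow(man), 9)
  for (r in seq_len(nrow(man))) {
    m <- man[r, ]
    expect_equal(codon_on_strand(coh$genomes[[m$genome_id]][[1]], m$pos,
                                 m$strand), m$codon)
  }
  # exactly one locus per gene per genome
  expect_equal(unname(table(man$genome_id, man$gene)),
               matrix(1L, 3, 3), ignore_attr = TRUE)
})

test_that("different seeds change the background but not the planted codon set", {
  genes <- list(planted_gene("a", 120, "GTG"))
  c1 <- generate_cohort(simulation_config(seed = 1, n_genomes = 1,
                                          contig_length = 2000, genes = genes))
  c2 <- generate_cohort(simulation_config(seed = 2, n_genomes = 1,
                                          contig_length = 2000, genes = genes))
  expect_false(identical(c1$genomes[[1]][[1]], c2$genomes[[1]][[1]]))
  expect_equal(c1$manifest$codon, c2$manifest$codon)
})

test_that("a planted secondary start is recoverable by re-scanning the emitted sequence", {
  g <- planted_gene("amb", 300, "GTG",
                    secondary_start = list(codon = "GTG", offset = 6))
  coh <- generate_cohort(simulation_config(seed = 5, n_genomes = 1,
                                           contig_length = 2000,
                                           genes = list(g)))
  m <- coh$manifest[1, ]
  contig <- coh$genomes[[1]][[1]]
  expect_equal(m$secondary_pos - m$pos, 6)
  expect_equal(codon_on_strand(contig, m$pos, m$strand), "GTG")
  expect_equal(codon_on_strand(contig, m$secondary_pos, m$strand), "GTG")
})

test_that("ATGTG overlap plants an out-of-frame ATG that terminates within five codons", {
  g <- planted_gene("ovl", 300, "GTG", atgtg_overlap = TRUE)
  coh <- generate_cohort(simulation_config(seed = 6, n_genomes = 1,
                                           contig_length = 2000,
                                           genes = list(g)))
  m <- coh$manifest[1, ]
  contig <- coh$genomes[[1]][[1]]
  expect_equal(substr(contig, m$pos - 1, m$pos + 3), "ATGTG")
  # read the ATG frame: a stop must appear within 5 codons
  frame <- substr(contig, m$pos - 1, m$pos - 1 + 17)
  codons <- substring(frame, seq(1, 16, 3), seq(3, 18, 3))
  expect_equal(codons[1], "ATG")
  expect_true(any(codons[2:5] %in% c("TAA", "TAG", "TGA")))
})

test_that("background composition matches the configured GC within 0.02 on a 50 kb contig", {
  coh <- generate_cohort(simulation_config(
    seed = 3, n_genomes = 1, contig_length = 50000, gc_content = 0.4,
    genes = list(planted_gene("a", 120, "ATG"))))
  chars <- strsplit(coh$genomes[[1]][[1]], "")[[1]]
  gc <- mean(chars %in% c("G", "C"))
  expect_lt(abs(gc - 0.4), 0.02)
})

test_that("invalid gene specs and undersized contigs are rejected", {
  expect_error(planted_gene("x", 100, "ATG"), "multiple of 3")
  expect_error(planted_gene("x", 30, "ATG"), ">= 60")
  expect_error(planted_gene("x", 120, "CTG"), "start_codon")
  expect_error(planted_gene("x", 120, "GTG",
                            secondary_start = list(codon = "GTG", offset = 5)),
               "multiple of 3")
  expect_error(generate_cohort(simulation_config(
    seed = 1, n_genomes = 1, contig_length = 200,
    genes = list(planted_gene("a", 120, "ATG")))), "too small")
})

test_that("divergence never mutates planted starts, stops or SD motifs", {
  g <- planted_gene("a", 120, "GTG", sd_motif = "AGGAGG", sd_spacer = 7)
  coh <- generate_cohort(simulation_config(seed = 8, n_genomes = 6,
                                           contig_length = 2000,
                                           genes = list(g),
                                           divergence_rate = 0.2))
  for (r in seq_len(nrow(coh$manifest))) {
    m <- coh$manifest[r, ]
    contig <- coh$genomes[[m$genome_id]][[1]]
    expect_equal(codon_on_strand(contig, m$pos, m$strand), "GTG")
    # SD motif intact at the recorded spacer upstream of the start
    sd_from <- m$pos - m$spacer - 6
    expect_equal(substr(contig, sd_from + 1, sd_from + 6), "AGGAGG")
    # stop codon intact at the end of the ORF
    stop_pos <- m$pos + m$orf_length - 3
    expect_true(codon_on_strand(contig, stop_pos, m$strand) %in%
                  c("TAA", "TAG", "TGA"))
  }
})

test_that("diverged planted ORFs stay free of premature in-frame stops", {
  g <- planted_gene("a", 300, "GTG")
  coh <- generate_cohort(simulation_config(seed = 9, n_genomes = 20,
                                           contig_length = 2000,
                                           genes = list(g),
                                           divergence_rate = 0.05))
  for (r in seq_len(nrow(coh$manifest))) {
    m <- coh$manifest[r, ]
    contig <- coh$genomes[[m$genome_id]][[1]]
    orf <- substr(contig, m$pos + 1, m$pos + m$orf_length)
    codons <- substring(orf, seq(1, m$orf_length - 2, 3),
                        seq(3, m$orf_length, 3))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("a minus-strand gene mirrors onto the reverse-complemented contig", {
  g <- planted_gene("rev", 120, "GTG", strand = "-")
  coh <- generate_cohort(simulation_config(seed = 10, n_genomes = 1,
                                           contig_length = 2000,
                                           genes = list(g)))
  m <- coh$manifest[1, ]
  contig <- coh$genomes[[1]][[1]]
  L <- nchar(contig)
  rc <- revcomp(contig)
  mirrored <- L - m$pos - 3
  expect_equal(substr(rc, mirrored + 1, mirrored + 3), "GTG")
})

test_that("metadata defaults are clean and overrides are honored", {
  ov <- data.frame(genome_id = "g001", completeness = 80, n_contigs = 500L)
  coh <- generate_cohort(simulation_config(
    seed = 11, n_genomes = 3, contig_length = 2000,
    genes = list(planted_gene("a", 120, "ATG")), metadata = ov))
  md <- coh$metadata
  expect_equal(md$completeness, c(100, 80, 100))
  expect_equal(md$n_contigs, c(1L, 500L, 1L))
  expect_equal(md$contamination, rep(0, 3))
})

test_that("identical config and seed give byte-identical artifacts on disk", {
  cfg <- simulation_config(seed = 12, n_genomes = 3, contig_length = 2000,
                           genes = list(planted_gene("a", 120, "GTG")),
                           divergence_rate = 0.02)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
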