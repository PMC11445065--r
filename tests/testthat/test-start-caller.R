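test_that("a single in-frame start and its stop give one candidate", {
  region <- make_region(paste0("CCC", "ATG", "AAA", "TAA", "CCC"),
                        hit_offset = 3L)
  cand <- enumerate_candidates(region)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$codon, "ATG")
  expect_equal(cand$pos, 3)
  expect_equal(cand$stop_pos, 9)
  expect_equal(cand$orf_length, 9)
})

test_that("a secondary in-frame start shares the stop of the primary", {
  g <- planted_gene("amb", 300, "GTG",
                    secondary_start = list(codon = "GTG", offset = 6))
  coh <- generate_cohort(simulation_config(seed = 21, n_genomes = 1,
                                           contig_length = 2000,
                                           genes = list(g)))
  refs <- cohort_references(coh)
  contig <- coh$genomes[[1]][[1]]
  bh <- best_hit(align_local(refs$sequence[1], contig, contig_id = "c"))
  region <- extract_flanked_region(contig, bh)
  cand <- enumerate_candidates(region)
  gtg <- cand[cand$codon == "GTG", ]
  expect_gte(nrow(gtg), 2)
  expect_true(6 %in% diff(gtg$pos))
  expect_equal(length(unique(cand$stop_pos)), 1)
})

test_that("the out-of-frame ATG of an ATGTG locus is not a candidate", {
  g <- planted_gene("ovl", 300, "GTG", atgtg_overlap = TRUE)
  coh <- generate_cohort(simulation_config(seed = 22, n_genomes = 1,
                                           contig_length = 2000,
                                           genes = list(g)))
  refs <- cohort_references(coh)
  contig <- coh$genomes[[1]][[1]]
  bh <- best_hit(align_local(refs$sequence[1], contig, contig_id = "c"))
  region <- extract_flanked_region(contig, bh)
  cand <- enumerate_candidates(region)
  planted <- region$hit_offset
  expect_true(planted %in% cand$pos)
  expect_equal(cand$codon[cand$pos == planted], "GTG")
  expect_false((planted - 2) %in% cand$pos)  # the overlapping ATG frame
})

test_that("a region with no downstream in-frame stop is flagged, not an error", {
  region <- make_region(paste0("CCC", "ATG", strrep("AAA", 10)),
                        hit_offset = 3L)
  cand <- enumerate_candidates(region)
  expect_equal(nrow(cand), 0)
  expect_true(isTRUE(attr(cand, "no_stop")))
  call <- resolve_starts(cand, hit_length = 30)
  expect_true("no_candidate" %in% call$flags)
  expect_equal(sum(call$weights), 0)
})

test_that("score differences between codons equal the start-weight differences", {
  model <- fixture_model()
  up <- strrep("C", 30)
  mk <- function(codon) {
    region <- make_region(paste0(up, codon, "AAA", "TAA"), hit_offset = 30L)
    score_candidates(enumerate_candidates(region), model, region)
  }
  a <- mk("ATG"); g <- mk("GTG")
  expect_equal(a$total_score - g$total_score,
               unname(model$start_weights[["ATG"]] -
                        model$start_weights[["GTG"]]))
  expect_equal(a$rbs_score, g$rbs_score)
})

test_that("a planted SD beats a pyrimidine upstream and matches a direct table scan", {
  model <- fixture_model()
  sd_up <- paste0(strrep("C", 17), "AGGAGG", strrep("C", 7))  # spacer 7
  ct_up <- strrep("CT", 15)
  mk <- function(up) {
    region <- make_region(paste0(up, "ATG", "AAA", "TAA"),
                          hit_offset = nchar(up))
    score_candidates(enumerate_candidates(region), model, region)
  }
  s_sd <- mk(sd_up); s_ct <- mk(ct_up)
  expect_gt(s_sd$rbs_score, s_ct$rbs_score)
  expect_true(s_sd$rbs_present)
  expect_false(s_ct$rbs_present)
  # oracle: exhaustive scan over every k-mer/spacer the model can score
  scan_best <- function(up) {
    best <- -Inf
    for (k in model$k_range) {
      for (s in 3:15) {
        if (s + k > nchar(up)) next
        kmer <- substr(up, nchar(up) - s - k + 1, nchar(up) - s)
        lo <- rbs_logodds(model, kmer, s)
        if (!is.na(lo)) best <- max(best, lo)
      }
    }
    best
  }
  expect_equal(s_sd$rbs_score, scan_best(sd_up))
  expect_equal(s_ct$rbs_score, scan_best(ct_up))
})

test_that("fractional counting splits retained candidates by codon class", {
  sc <- make_scored(c("ATG", "GTG", "GTG"), total_score = c(5, 5, 5),
                    orf_length = c(300, 300, 294))
  call <- resolve_starts(sc, hit_length = 300)
  expect_equal(call$n_retained, 3)
  expect_equal(unname(call$counts[c("ATG", "GTG")]), c(1L, 2L))
  expect_equal(call$weights[["GTG"]], 2 / 3)
  expect_equal(call$weights[["ATG"]], 1 / 3)
  expect_equal(trunc2(call$weights[["GTG"]]), 0.66)
  expect_equal(trunc2(call$weights[["ATG"]]), 0.33)

  single <- resolve_starts(make_scored("ATG", 5, 300), hit_length = 300)
  expect_equal(single$weights[["ATG"]], 1.0)
})

test_that("the 80%-of-best score rule drops weaker candidates after the shift", {
  sc <- make_scored(c("ATG", "GTG"), total_score = c(10, 7.9),
                    orf_length = c(300, 300), rbs_present = TRUE)
  call <- resolve_starts(sc, hit_length = 300)
  expect_equal(call$n_retained, 1)
  expect_equal(call$retained$codon, "ATG")
  # with negative scores the shift keeps the rule well defined
  sc2 <- make_scored(c("ATG", "GTG"), total_score = c(2, -3),
                     orf_length = c(300, 300))
  call2 <- resolve_starts(sc2, hit_length = 300)
  expect_equal(call2$retained$codon, "ATG")
})

test_that("short ORFs are dropped as fragmented before scoring rules apply", {
  sc <- make_scored(c("ATG", "GTG"), total_score = c(10, 100),
                    orf_length = c(300, 200))
  call <- resolve_starts(sc, hit_length = 300)
  expect_equal(call$retained$codon, "ATG")
  expect_true("fragmented" %in% call$flags)
})

test_that("RBS consistency removes alternatives when the top start has an RBS", {
  sc <- make_scored(c("GTG", "ATG"), total_score = c(10, 9.5),
                    orf_length = c(300, 300),
                    rbs_present = c(TRUE, FALSE))
  call <- resolve_starts(sc, hit_length = 300)
  expect_equal(call$retained$codon, "GTG")
  expect_true("rbs_filtered" %in% call$flags)
  # ... but not when the top start itself lacks an RBS
  sc2 <- make_scored(c("GTG", "ATG"), total_score = c(10, 9.5),
                     orf_length = c(300, 300),
                     rbs_present = c(FALSE, TRUE))
  call2 <- resolve_starts(sc2, hit_length = 300)
  expect_equal(sort(call2$retained$codon), c("ATG", "GTG"))
})

test_that("every retained candidate satisfies all three rules and exclusions are justified", {
  set.seed(30)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    sc <- make_scored(sample(c("ATG", "GTG", "TTG"), n, replace = TRUE),
                      total_score = round(runif(n, -5, 10), 2),
                      orf_length = sample(c(180, 250, 280, 300), n,
                                          replace = TRUE),
                      rbs_present = sample(c(TRUE, FALSE), n, replace = TRUE))
    call <- resolve_starts(sc, hit_length = 300)
    long <- sc[sc$orf_length >= 0.9 * 300, , drop = FALSE]
    if (nrow(long) == 0) {
      expect_true("no_candidate" %in% call$flags)
      next
    }
    shift <- -min(0, min(long$total_score)) + 1e-9
    kept <- long[(long$total_score + shift) >=
                   0.8 * max(long$total_score + shift), , drop = FALSE]
    top <- kept[which.max(kept$total_score), ]
    if (top$rbs_present) kept <- kept[kept$rbs_present, , drop = FALSE]
    expect_equal(sort(call$retained$pos), sort(kept$pos))
    # weights sum to one exactly in counts, 1e-12 in doubles
    expect_identical(sum(call$counts), call$n_retained)
    expect_lt(abs(sum(call$weights) - 1), 1e-12)
  }
})

test_that("rule order is configurable and invariant on typical candidate sets", {
  set.seed(35)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    sc <- make_scored(sample(c("ATG", "GTG", "TTG"), n, replace = TRUE),
                      total_score = round(runif(n, 0, 10), 1),
                      orf_length = sample(c(280, 290, 300), n, replace = TRUE),
                      rbs_present = TRUE)
    a <- resolve_starts(sc, hit_length = 300, rule_order = "length_first")
    b <- resolve_starts(sc, hit_length = 300, rule_order = "score_first")
    expect_equal(a$weights, b$weights)
  }
  # ... and differs only when a long, weak candidate shields a short one
  sc <- make_scored(c("ATG", "GTG"), total_score = c(2, 10),
                    orf_length = c(300, 200))
  lf <- resolve_starts(sc, hit_length = 300, rule_order = "length_first")
  expect_equal(lf$retained$codon, "ATG")
})

test_that("ties in total score fractionate rather than break arbitrarily", {
  sc <- make_scored(c("ATG", "GTG"), total_score = c(5, 5),
                    orf_length = c(300, 300))
  call <- resolve_starts(sc, hit_length = 300)
  expect_equal(call$n_retained, 2)
  expect_equal(call$weights[["ATG"]], 0.5)
  expect_equal(call$weights[["GTG"]], 0.5)
})
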