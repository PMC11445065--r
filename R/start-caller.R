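#' Enumerate in-frame candidate start codons in a flanked region
#'
#' Lists every ATG/GTG/TTG triplet that lies in the reading frame of the
#' homology hit, downstream of any upstream in-frame stop and upstream of
#' the shared in-frame stop closing the gene, sorted by position. The frame
#' is anchored at `hit_offset - qstart` so that a hit whose alignment clips
#' the query 5' end still indexes the gene's codon lattice.
#'
#' @param region a `flanked_region` from [extract_flanked_region()].
#' @param qstart query-start offset of the hit (defaults to the value
#'   recorded in `region`).
#' @return data frame with columns `pos`, `codon`, `stop_pos`, `orf_length`
#'   and `frame_anchor` (all positions 0-based within the region). When no
#'   in-frame stop exists downstream of the hit the result is empty with
#'   attribute `no_stop = TRUE`.
#' @export
enumerate_candidates <- function(region, qstart = NULL) {
  stopifnot(inherits(region, "flanked_region"))
  qstart <- qstart %||% (region$qstart %||% 0L)
  seq <- region$sequence
  L <- nchar(seq)
  anchor <- (region$hit_offset - qstart) %% 3L
  frame_pos <- seq.int(anchor, L - 3L, by = 3L)
  triplets <- substring(seq, frame_pos + 1L, frame_pos + 3L)
  stop_idx <- frame_pos[triplets %in% STOP_CODONS]
  shared_stop <- stop_idx[stop_idx >= region$hit_offset]
  if (length(shared_stop) == 0) {
    out <- data.frame(pos = integer(0), codon = character(0),
                      stop_pos = integer(0), orf_length = integer(0),
                      frame_anchor = integer(0))
    attr(out, "no_stop") <- TRUE
    return(out)
  }
  shared_stop <- shared_stop[1]
  lower <- stop_idx[stop_idx < shared_stop]
  lower <- if (length(lower) > 0) max(lower) else -3L
  keep <- frame_pos > lower & frame_pos < shared_stop &
    triplets %in% START_CODONS
  out <- data.frame(pos = frame_pos[keep], codon = triplets[keep],
                    stop_pos = shared_stop,
                    orf_length = shared_stop + 3L - frame_pos[keep],
                    frame_anchor = anchor, stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

#' Score candidate starts with a trained model
#'
#' For each candidate, `rbs_score` is the maximum RBS log-odds over all
#' k-mer sizes and spacer positions covered by the model's spacer bins
#' within the upstream context available in the region; `start_score` is the
#' model's log-frequency of the candidate codon; `total_score` is their
#' sum. Candidates with less upstream context than the largest spacer
#' window are scored over the available window and flagged `truncated`; a
#' candidate with no scorable window gets `rbs_score` 0 and
#' `rbs_present = FALSE`.
#'
#' @param candidates data frame from [enumerate_candidates()].
#' @param model a `start_model`.
#' @param region the `flanked_region` the candidates were enumerated in.
#' @return `candidates` with columns `rbs_score`, `rbs_present`,
#'   `start_score`, `total_score`, `truncated` appended.
#' @export
score_candidates <- function(candidates, model, region) {
  stopifnot(inherits(model, "start_model"))
  n <- nrow(candidates)
  rbs_score <- numeric(n)
  rbs_present <- logical(n)
  truncated <- logical(n)
  seq <- region$sequence
  max_span <- max(model$spacer_bins[, "hi"]) - 1L + max(model$k_range)
  smin <- min(model$spacer_bins[, "lo"])
  smax <- max(model$spacer_bins[, "hi"]) - 1L
  for (i in seq_len(n)) {
    p <- candidates$pos[i]
    truncated[i] <- p < max_span
    best <- NA_real_
    for (k in model$k_range) {
      for (s in smin:smax) {
        if (s + k > p) next
        kmer <- substr(seq, p - s - k + 1L, p - s)
        lo <- rbs_logodds(model, kmer, s)
        if (!is.na(lo) && (is.na(best) || lo > best)) best <- lo
      }
    }
    rbs_score[i] <- if (is.na(best)) 0 else best
    rbs_present[i] <- !is.na(best) && best >= model$rbs_present_threshold
  }
  candidates$rbs_score <- rbs_score
  candidates$rbs_present <- rbs_present
  candidates$start_score <- unname(model$start_weights[candidates$codon])
  candidates$total_score <- candidates$rbs_score + candidates$start_score
  candidates$truncated <- truncated
  candidates
}

new_start_call <- function(genome_id, gene, retained, counts, flags) {
  k <- sum(counts)
  weights <- if (k > 0) counts / k else stats::setNames(rep(0, 4), CODON_CLASSES)
  structure(list(genome_id = genome_id, gene = gene, retained = retained,
                 counts = counts, n_retained = k, weights = weights,
                 flags = flags),
            class = "start_call")
}

#' Resolve ambiguous start candidates into a fractional call
#'
#' Applies the three disambiguation rules: (1) drop candidates whose ORF
#' spans less than `len_frac` of the homology hit length (fragmented
#' proteins); (2) keep candidates whose total score is within `score_ratio`
#' of the best survivor, after shifting all scores by `-min(0, min score) +
#' eps` so the ratio operates on non-negative values; (3) if the top
#' survivor has a predicted RBS, drop alternatives without one. Each of the
#' k retained candidates then contributes 1/k to its codon class.
#'
#' @param scored data frame from [score_candidates()].
#' @param hit_length aligned subject span of the homology hit, in nt.
#' @param score_ratio retention ratio (default 0.8).
#' @param len_frac minimum ORF length as a fraction of `hit_length`
#'   (default 0.9).
#' @param genome_id,gene identifiers carried into the call.
#' @param eps positive shift guard (default 1e-9).
#' @param rule_order `"length_first"` (default) applies the ORF-length rule
#'   before the score-ratio rule; `"score_first"` reverses them. The two
#'   orders coincide whenever no candidate is dropped by both rules jointly;
#'   the default pipeline data is order-invariant.
#' @return an object of class `start_call` with exact integer class
#'   `counts`, derived `weights` over `{ATG, GTG, TTG, other}`, and `flags`
#'   among `no_candidate`, `fragmented`, `rbs_filtered`.
#' @export
resolve_starts <- function(scored, hit_length, score_ratio = 0.8,
                           len_frac = 0.9, genome_id = NA_character_,
                           gene = NA_character_, eps = 1e-9,
                           rule_order = c("length_first", "score_first")) {
  rule_order <- match.arg(rule_order)
  flags <- character(0)
  if (isTRUE(attr(scored, "no_stop"))) flags <- c(flags, "no_stop")
  counts0 <- stats::setNames(rep(0L, 4L), CODON_CLASSES)
  if (nrow(scored) == 0) {
    return(new_start_call(genome_id, gene, scored, counts0,
                          c(flags, "no_candidate")))
  }
  length_rule <- function(df) {
    keep <- df$orf_length >= len_frac * hit_length
    if (any(!keep)) flags <<- c(flags, "fragmented")
    df[keep, , drop = FALSE]
  }
  score_rule <- function(df) {
    if (nrow(df) == 0) return(df)
    shifted <- df$total_score - min(0, min(df$total_score)) + eps
    df[shifted >= score_ratio * max(shifted), , drop = FALSE]
  }
  surv <- if (rule_order == "length_first") {
    score_rule(length_rule(scored))
  } else {
    length_rule(score_rule(scored))
  }
  if (nrow(surv) == 0) {
    return(new_start_call(genome_id, gene, surv, counts0,
                          c(flags, "no_candidate")))
  }
  top <- surv[which.max(surv$total_score), , drop = FALSE]
  if (top$rbs_present && any(!surv$rbs_present)) {
    flags <- c(flags, "rbs_filtered")
    surv <- surv[surv$rbs_present, , drop = FALSE]
  }
  cls <- ifelse(surv$codon %in% START_CODONS, surv$codon, "other")
  counts <- counts0
  tab <- table(factor(cls, levels = CODON_CLASSES))
  counts[names(tab)] <- as.integer(tab)
  new_start_call(genome_id, gene, surv, counts, flags)
}

#' @export
print.start_call <- function(x, ...) {
  cat("Start call", if (!is.na(x$gene)) paste0("for ", x$gene),
      if (!is.na(x$genome_id)) paste0("in ", x$genome_id), "\n")
  if (x$n_retained == 0) {
    cat("  no retained candidates; flags:",
        paste(x$flags, collapse = ", "), "\n")
  } else {
    w <- x$weights[x$weights > 0]
    cat("  ", paste(sprintf("%s = %.2f", names(w), trunc2(w)),
                    collapse = ", "), "\n", sep = "")
    if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Call start codons for every reference gene in one genome
#'
#' Composes the full per-genome procedure: locate each reference gene by
#' local alignment over all contigs, excise the best hit with flanks,
#' enumerate and score candidate starts, and resolve them into a fractional
#' call. Genes without a reportable hit are flagged `absent`; per-gene
#' failures (e.g. no in-frame stop) are flagged, never propagated as
#' errors.
#'
#' @param genome named character vector / `DNAStringSet` of contigs, or a
#'   FASTA path.
#' @param references a [reference_genes()] data frame.
#' @param model a trained `start_model`.
#' @param scoring an [alignment_scoring()].
#' @param flank flank size in nt (default 75).
#' @param genome_id identifier recorded in the calls.
#' @param score_ratio,len_frac resolution parameters, see
#'   [resolve_starts()].
#' @return data frame with one row per reference gene: `genome_id`, `gene`,
#'   `ATG`, `GTG`, `TTG`, `other` (fractions), `n_retained`, `flags`
#'   (semicolon-joined). The list of `start_call` objects is attached as
#'   attribute `"calls"`.
#' @export
call_genome <- function(genome, references, model,
                        scoring = alignment_scoring(), flank = 75L,
                        genome_id = NA_character_, score_ratio = 0.8,
                        len_frac = 0.9) {
  genome <- load_genome(genome)
  calls <- vector("list", nrow(references))
  for (i in seq_len(nrow(references))) {
    gene <- references$name[i]
    query <- references$sequence[i]
    hits <- lapply(names(genome), function(cid) {
      align_local(query, genome[[cid]], scoring,
                  genome_id = genome_id, contig_id = cid)
    })
    hits <- do.call(rbind, hits)
    bh <- best_hit(hits)
    if (is.null(bh)) {
      counts0 <- stats::setNames(rep(0L, 4L), CODON_CLASSES)
      calls[[i]] <- new_start_call(genome_id, gene, NULL, counts0, "absent")
      next
    }
    region <- extract_flanked_region(genome[[bh$contig_id]], bh, flank)
    cand <- enumerate_candidates(region)
    scored <- if (nrow(cand) > 0) score_candidates(cand, model, region) else cand
    calls[[i]] <- resolve_starts(scored, hit_length = bh$hit_length,
                                 score_ratio = score_ratio,
                                 len_frac = len_frac,
                                 genome_id = genome_id, gene = gene)
  }
  out <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(genome_id = cl$genome_id, gene = cl$gene,
               ATG = cl$weights[["ATG"]], GTG = cl$weights[["GTG"]],
               TTG = cl$weights[["TTG"]], other = cl$weights[["other"]],
               n_retained = cl$n_retained,
               flags = paste(cl$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  out
}

#' Call start codons across a cohort of genomes
#'
#' @param genomes named list of genomes (each a named character vector of
#'   contigs), or a `sim_cohort`.
#' @param references,model,scoring,flank,score_ratio,len_frac passed to
#'   [call_genome()].
#' @return row-bound calls data frame (one row per genome x gene).
#' @export
call_cohort <- function(genomes, references, model,
                        scoring = alignment_scoring(), flank = 75L,
                        score_ratio = 0.8, len_frac = 0.9) {
  if (inherits(genomes, "sim_cohort")) genomes <- genomes$genomes
  out <- lapply(names(genomes), function(id) {
    res <- call_genome(genomes[[id]], references, model, scoring, flank,
                       genome_id = id, score_ratio = score_ratio,
                       len_frac = len_frac)
    attr(res, "calls") <- NULL
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write per-genome calls to TSV
#'
#' @param calls calls data frame from [call_cohort()] / [call_genome()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
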