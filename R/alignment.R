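#' Alignment scoring scheme for the homology locator
#'
#' Parameters of the affine-gap Smith-Waterman search used to locate
#' reference regulator genes in genome contigs. A gap of length L costs
#' `gap_open + L * gap_extend`. The score floor `min_report_score` replaces
#' an E-value cutoff; when `NULL` it defaults to `0.6 * match * nchar(query)`
#' at alignment time.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0); `N` bases always score as mismatch.
#' @param gap_open gap opening score (< 0).
#' @param gap_extend per-base gap extension score (< 0).
#' @param min_report_score minimum alignment score to report, or `NULL` for
#'   the query-length default.
#' @param max_hits maximum number of hits returned per subject scan.
#' @return an object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                              gap_extend = -2L, min_report_score = NULL,
                              max_hits = 100L) {
  if (match <= 0) stop("match score must be positive", call. = FALSE)
  if (mismatch >= 0 || gap_open >= 0 || gap_extend >= 0) {
    stop("mismatch and gap penalties must be negative", call. = FALSE)
  }
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_report_score = min_report_score,
                 max_hits = as.integer(max_hits)),
            class = "alignment_scoring")
}

empty_hits <- function() {
  data.frame(genome_id = character(0), contig_id = character(0),
              sstart = integer(0), send = integer(0), strand = character(0),
              score = integer(0), identity = numeric(0),
              qstart = integer(0), qend = integer(0),
              hit_length = integer(0), stringsAsFactors = FALSE)
}

# One iterated-masking pass over a single strand. `seq_chars` is modified
# between iterations by masking reported spans with N.
sw_strand_hits <- function(query, subject, scoring, floor_score, max_hits) {
  qlen <- nchar(query)
  slen <- nchar(subject)
  hits <- list()
  subj <- subject
  for (k in seq_len(max_hits)) {
    scan <- sw_scan_cpp(query, subj, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_extend)
    if (scan[1] < floor_score || scan[1] <= 0) break
    send <- scan[3]
    ws <- max(0L, send - (2L * qlen + 64L))
    window <- substr(subj, ws + 1L, send)
    al <- sw_align_cpp(query, window, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
    sstart <- ws + al$sstart
    send2 <- ws + al$send
    hits[[k]] <- list(sstart = sstart, send = send2, score = al$score,
                      identity = al$nmatch / max(1L, al$ncols),
                      qstart = al$qstart, qend = al$qend,
                      hit_length = send2 - sstart)
    # mask the reported subject span so further passes find other loci
    substr(subj, sstart + 1L, send2) <- strrep("N", send2 - sstart)
  }
  hits
}

#' Local alignment of a query gene against a subject sequence
#'
#' Scans both strands of `subject` with an exact affine-gap Smith-Waterman
#' and reports local hits above the score floor, best first. Multiple hits
#' are recovered by masking each reported span and re-scanning. Coordinates
#' are 0-based half-open on the forward strand of the subject; `strand` is
#' the strand on which the query matches.
#'
#' @param query,subject DNA strings (`A/C/G/T/N`).
#' @param scoring an [alignment_scoring()] object.
#' @param genome_id,contig_id identifiers copied into the hit table.
#' @return a data frame of hits with columns `genome_id`, `contig_id`,
#'   `sstart`, `send`, `strand`, `score`, `identity`, `qstart`, `qend` and
#'   `hit_length`, sorted by decreasing score (ties: smaller `sstart`, then
#'   `+` strand, then `contig_id`).
#' @export
align_local <- function(query, subject, scoring = alignment_scoring(),
                        genome_id = NA_character_, contig_id = NA_character_) {
  query <- check_dna(query, "query")
  subject <- check_dna(subject, "subject")
  floor_score <- scoring$min_report_score %||% (0.6 * scoring$match * nchar(query))
  out <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") subject else revcomp(subject)
    hs <- sw_strand_hits(query, subj, scoring, floor_score, scoring$max_hits)
    for (h in hs) {
      if (strand == "-") {
        L <- nchar(subject)
        tmp <- h$sstart
        h$sstart <- L - h$send
        h$send <- L - tmp
      }
      out[[length(out) + 1L]] <- data.frame(
        genome_id = genome_id, contig_id = contig_id,
        sstart = h$sstart, send = h$send, strand = strand,
        score = h$score, identity = h$identity,
        qstart = h$qstart, qend = h$qend, hit_length = h$hit_length,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(-hits$score, hits$sstart, hits$strand,
                     hits$contig_id, method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL
  utils::head(hits, scoring$max_hits)
}

#' Best hit among homology hits
#'
#' Highest score wins; ties are broken by smaller `sstart`, then `+` strand,
#' then lexicographic `contig_id`.
#'
#' @param hits a hit data frame from [align_local()].
#' @return a one-row data frame, or `NULL` when `hits` is empty.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  ord <- order(-hits$score, hits$sstart, hits$strand, hits$contig_id,
               method = "radix")
  hits[ord[1], , drop = FALSE]
}

#' Excise a hit with flanking sequence, in gene-sense orientation
#'
#' Cuts the aligned span plus up to `flank` nucleotides on either side out of
#' the contig. For `-` strand hits the window is reverse-complemented so the
#' emitted sequence reads 5' to 3' in the orientation of the query gene.
#' Recorded flank sizes reflect clipping at contig edges; `hit_offset` is the
#' 0-based position of the hit start within the emitted sequence (equal to
#' the obtained 5' flank).
#'
#' @param contig DNA string of the contig the hit lies on.
#' @param hit one-row hit data frame (see [align_local()]).
#' @param flank maximum flank length in nucleotides (default 75).
#' @return an object of class `flanked_region`: a list with `sequence`,
#'   `window_start`, `window_end`, `hit_offset`, `left_flank`, `right_flank`,
#'   `qstart`, `hit_length` and `source`.
#' @export
extract_flanked_region <- function(contig, hit, flank = 75L) {
  contig <- check_dna(contig, "contig")
  L <- nchar(contig)
  if (hit$sstart < 0 || hit$send > L || hit$sstart >= hit$send) {
    stop("hit coordinates lie outside the contig", call. = FALSE)
  }
  ws <- max(0L, hit$sstart - flank)
  we <- min(L, hit$send + flank)
  seq <- substr(contig, ws + 1L, we)
  if (hit$strand == "-") {
    seq <- revcomp(seq)
    left <- we - hit$send
    right <- hit$sstart - ws
  } else {
    left <- hit$sstart - ws
    right <- we - hit$send
  }
  structure(list(sequence = seq, window_start = ws, window_end = we,
                 hit_offset = left, left_flank = left, right_flank = right,
                 qstart = hit$qstart, hit_length = hit$send - hit$sstart,
                 source = list(genome_id = hit$genome_id,
                               contig_id = hit$contig_id,
                               strand = hit$strand)),
            class = "flanked_region")
}
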