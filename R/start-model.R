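DEFAULT_SPACER_BINS <- cbind(lo = c(3L, 5L, 7L, 9L, 11L, 13L),
                             hi = c(5L, 7L, 9L, 11L, 13L, 16L))

spacer_bin_index <- function(spacer, bins) {
  hit <- which(spacer >= bins[, "lo"] & spacer < bins[, "hi"])
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Train the start-codon / ribosome-binding-site model
#'
#' Estimates, from an annotated training genome, (i) log-frequencies of the
#' three start codons at annotated gene starts (add-one smoothing over the
#' three-codon alphabet) and (ii) a log-odds table of Shine-Dalgarno k-mers
#' (k = 3..6) by spacer bin: `log(P(kmer at that spacer | true start) /
#' P(kmer | background))`, add-one smoothed, with the background given by
#' the genome's nucleotide composition under an i.i.d. model. The spacer is
#' the distance in nucleotides between the k-mer 3' end and the start codon.
#'
#' @param genome named character vector / `DNAStringSet` of contigs, or a
#'   path to a FASTA file.
#' @param annotation data frame with columns `seqid`, `start`, `end`
#'   (1-based inclusive), `strand`, `name`, or a path to a GFF3 file of
#'   gene features.
#' @param spacer_bins two-column integer matrix of half-open spacer ranges.
#' @param k_range k-mer sizes scored (default 3:6).
#' @param rbs_present_threshold minimum RBS log-odds counted as "has an
#'   RBS". Because the RBS score is a maximum over many (k-mer, spacer)
#'   lookups, motif-free upstreams reach ~ +0.35 by chance under the
#'   background model; the default of 1 sits above that chance level and
#'   far below planted-motif scores.
#' @param min_genes minimum usable training genes (default 50).
#' @return an object of class `start_model`.
#' @export
train_start_model <- function(genome, annotation,
                              spacer_bins = DEFAULT_SPACER_BINS,
                              k_range = 3:6, rbs_present_threshold = 1,
                              min_genes = 50L) {
  genome <- load_genome(genome)
  annotation <- load_annotation(annotation)
  max_span <- max(spacer_bins[, "hi"]) - 1L + max(k_range)
  upstream_min <- 16L
  usable <- 0L
  start_counts <- stats::setNames(rep(0L, 3L), START_CODONS)
  obs <- list()  # one data.frame(k, bin, kmer) chunk per gene
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    contig <- genome[[a$seqid]]
    if (is.null(contig)) stop("annotation references unknown contig ", a$seqid,
                              call. = FALSE)
    L <- nchar(contig)
    if (a$strand == "+") {
      codon <- substr(contig, a$start, a$start + 2L)
      ups <- max(1L, a$start - max_span)
      upstream <- substr(contig, ups, a$start - 1L)
    } else {
      codon <- revcomp(substr(contig, a$end - 2L, a$end))
      upe <- min(L, a$end + max_span)
      upstream <- revcomp(substr(contig, a$end + 1L, upe))
    }
    if (!codon %in% START_CODONS) next
    if (nchar(upstream) < upstream_min) next
    usable <- usable + 1L
    start_counts[codon] <- start_counts[codon] + 1L
    U <- nchar(upstream)
    rows <- list()
    for (k in k_range) {
      for (s in spacer_bins[1, "lo"]:(max(spacer_bins[, "hi"]) - 1L)) {
        bin <- spacer_bin_index(s, spacer_bins)
        if (is.na(bin) || s + k > U) next
        kmer <- substr(upstream, U - s - k + 1L, U - s)
        rows[[length(rows) + 1L]] <- c(k, bin, kmer)
      }
    }
    obs[[length(obs) + 1L]] <- rows
  }
  if (usable < min_genes) {
    stop("only ", usable, " usable training genes (need >= ", min_genes,
         "); supply a larger annotated training set", call. = FALSE)
  }
  flat <- do.call(rbind, lapply(obs, function(rs) do.call(rbind, rs)))
  counts <- as.data.frame(table(k = flat[, 1], bin = flat[, 2],
                                kmer = flat[, 3]), stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, , drop = FALSE]
  counts$k <- as.integer(counts$k)
  counts$bin <- as.integer(counts$bin)
  names(counts)[names(counts) == "Freq"] <- "count"
  totals <- stats::aggregate(count ~ k + bin, data = counts, FUN = sum)
  names(totals)[names(totals) == "count"] <- "total"
  all_seq <- paste(unlist(genome), collapse = "")
  tab <- table(factor(dna_chars(all_seq), levels = c("A", "C", "G", "T", "N")))
  acgt <- tab[c("A", "C", "G", "T")]
  background <- as.numeric(acgt) / sum(acgt)
  names(background) <- c("A", "C", "G", "T")
  model <- structure(list(
    version = "1",
    start_weights = log((start_counts + 1) / (usable + 3)),
    rbs_counts = counts[order(counts$k, counts$bin, counts$kmer), ,
                        drop = FALSE],
    rbs_totals = totals[order(totals$k, totals$bin), , drop = FALSE],
    spacer_bins = spacer_bins, k_range = as.integer(k_range),
    rbs_present_threshold = rbs_present_threshold,
    background = background, n_genes = usable,
    trained_on = paste(names(genome), collapse = ",")),
    class = "start_model")
  rebuild_lookup(model)
}

# attach fast hashed lookup environments (not serialized)
rebuild_lookup <- function(model) {
  env <- new.env(parent = emptyenv(), size = nrow(model$rbs_counts) * 2L)
  keys <- paste(model$rbs_counts$k, model$rbs_counts$bin,
                model$rbs_counts$kmer, sep = ":")
  for (i in seq_along(keys)) assign(keys[i], model$rbs_counts$count[i], envir = env)
  tot <- new.env(parent = emptyenv())
  tkeys <- paste(model$rbs_totals$k, model$rbs_totals$bin, sep = ":")
  for (i in seq_along(tkeys)) assign(tkeys[i], model$rbs_totals$total[i], envir = tot)
  model$count_env <- env
  model$total_env <- tot
  model
}

#' RBS log-odds of a k-mer at a given spacer
#'
#' @param model a `start_model`.
#' @param kmer DNA string of length within the model's `k_range`.
#' @param spacer nucleotides between the k-mer 3' end and the start codon.
#' @return log-odds (numeric), or `NA` when the spacer falls outside all
#'   bins.
#' @export
rbs_logodds <- function(model, kmer, spacer) {
  k <- nchar(kmer)
  if (!k %in% model$k_range) stop("kmer length outside model k_range", call. = FALSE)
  bin <- spacer_bin_index(spacer, model$spacer_bins)
  if (is.na(bin)) return(NA_real_)
  cnt <- mget(paste(k, bin, kmer, sep = ":"), envir = model$count_env,
              ifnotfound = 0L)[[1]]
  tot <- mget(paste(k, bin, sep = ":"), envir = model$total_env,
              ifnotfound = 0L)[[1]]
  p_fg <- (cnt + 1) / (tot + 4^k)
  p_bg <- prod(model$background[dna_chars(kmer)])
  log(p_fg / p_bg)
}

#' Observed cells of the RBS table as a data frame
#'
#' Returns the log-odds of every (k-mer, spacer-bin) cell observed in
#' training; unobserved cells share the smoothed baseline for their (k,
#' bin).
#'
#' @param model a `start_model`.
#' @return data frame with columns `k`, `bin`, `kmer`, `count`, `logodds`.
#' @export
rbs_table_df <- function(model) {
  df <- model$rbs_counts
  df$logodds <- vapply(seq_len(nrow(df)), function(i) {
    tot <- model$rbs_totals$total[model$rbs_totals$k == df$k[i] &
                                    model$rbs_totals$bin == df$bin[i]]
    p_fg <- (df$count[i] + 1) / (tot + 4^df$k[i])
    p_bg <- prod(model$background[dna_chars(df$kmer[i])])
    log(p_fg / p_bg)
  }, 0)
  df
}

#' Serialize / restore a start model as versioned JSON
#'
#' @param model a `start_model`.
#' @param path file path.
#' @return `write_start_model` invisibly returns `path`;
#'   `read_start_model` returns the restored `start_model`.
#' @export
write_start_model <- function(model, path) {
  obj <- model[c("version", "start_weights", "rbs_counts", "rbs_totals",
                 "k_range", "rbs_present_threshold", "background",
                 "n_genes", "trained_on")]
  obj$start_weights <- as.list(obj$start_weights)
  obj$background <- as.list(obj$background)
  obj$spacer_bins <- as.data.frame(model$spacer_bins)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_start_model
#' @export
read_start_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$version, "1")) {
    stop("unsupported start_model version: ", obj$version, call. = FALSE)
  }
  model <- structure(list(
    version = obj$version,
    start_weights = unlist(obj$start_weights),
    rbs_counts = as.data.frame(obj$rbs_counts),
    rbs_totals = as.data.frame(obj$rbs_totals),
    spacer_bins = as.matrix(obj$spacer_bins),
    k_range = as.integer(obj$k_range),
    rbs_present_threshold = obj$rbs_present_threshold,
    background = unlist(obj$background),
    n_genes = obj$n_genes, trained_on = obj$trained_on),
    class = "start_model")
  colnames(model$spacer_bins) <- c("lo", "hi")
  rebuild_lookup(model)
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome),
                              sub("\\s.*$", "", names(genome)))
  }
  if (inherits(genome, "sim_cohort")) {
    stop("pass a single genome, e.g. cohort$genomes[[1]]", call. = FALSE)
  }
  as.list(genome)
}

load_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1 &&
      file.exists(annotation)) {
    gr <- rtracklayer::import(annotation, format = "gff3")
    gr <- gr[gr$type == "gene"]
    annotation <- data.frame(
      seqid = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      name = if (!is.null(gr$Name)) gr$Name else gr$ID,
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("seqid", "start", "end", "strand", "name") %in%
                  colnames(annotation)))
  annotation
}
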