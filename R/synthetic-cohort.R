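NON_STOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Specification of a planted regulator gene
#'
#' Describes one regulator locus planted into every genome of a synthetic
#' cohort: ORF length, start codon, strand, the Shine-Dalgarno motif and its
#' spacer (nucleotides between the motif 3' end and the start codon), an
#' optional in-frame secondary start within ten nucleotides, and an optional
#' out-of-frame overlapping ATGTG configuration in which translation from the
#' ATG terminates within a few codons.
#'
#' @param name gene label.
#' @param orf_length ORF length in nucleotides, start through stop codon
#'   inclusive; must be a multiple of 3 and at least 60.
#' @param start_codon `"ATG"`, `"GTG"` or `"TTG"`. May be a vector with one
#'   codon per genome to plant different codons across a cohort.
#' @param strand `"+"` or `"-"`.
#' @param sd_motif Shine-Dalgarno motif planted upstream (default `AGGAGG`).
#' @param sd_spacer nucleotides between motif 3' end and start codon (>= 3).
#' @param secondary_start optional `list(codon =, offset =)` planting a
#'   second in-frame start; `offset` is relative to the primary start, a
#'   multiple of 3 with absolute value at most 10 (so -9..9).
#' @param atgtg_overlap plant an overlapping out-of-frame `ATGTG` so that the
#'   primary GTG is preceded by `AT`; the ATG frame hits a stop immediately.
#' @param category `"carbohydrate"` or `"non-carbohydrate"`.
#' @param mode regulatory mode: `"positive"`, `"negative"` or
#'   `"bidirectional"`.
#' @return an object of class `planted_gene`.
#' @export
planted_gene <- function(name, orf_length = 300L, start_codon = "GTG",
                         strand = "+", sd_motif = "AGGAGG", sd_spacer = 7L,
                         secondary_start = NULL, atgtg_overlap = FALSE,
                         category = "carbohydrate", mode = "negative") {
  if (orf_length %% 3 != 0) {
    stop("orf_length of '", name, "' is not a multiple of 3", call. = FALSE)
  }
  if (orf_length < 60) stop("orf_length must be >= 60", call. = FALSE)
  if (!all(start_codon %in% START_CODONS)) {
    stop("start_codon must be one of ", paste(START_CODONS, collapse = "/"),
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  sd_motif <- check_dna(sd_motif, "sd_motif", allow_n = FALSE)
  if (sd_spacer < 3) stop("sd_spacer must be >= 3", call. = FALSE)
  if (!is.null(secondary_start)) {
    off <- secondary_start$offset
    if (is.null(off) || off %% 3 != 0 || abs(off) > 10 || off == 0) {
      stop("secondary_start offset must be a non-zero multiple of 3 within ",
           "ten nucleotides of the primary start", call. = FALSE)
    }
    if (!secondary_start$codon %in% START_CODONS) {
      stop("secondary_start codon must be one of ",
           paste(START_CODONS, collapse = "/"), call. = FALSE)
    }
    if (off > 0 && off >= orf_length - 3) {
      stop("secondary_start offset lies beyond the ORF", call. = FALSE)
    }
    if (atgtg_overlap && off < 0) {
      stop("atgtg_overlap cannot be combined with an upstream secondary start",
           call. = FALSE)
    }
  }
  if (atgtg_overlap && !all(start_codon == "GTG")) {
    stop("atgtg_overlap requires a GTG primary start codon", call. = FALSE)
  }
  structure(list(name = name, orf_length = as.integer(orf_length),
                 start_codon = start_codon, strand = strand,
                 sd_motif = sd_motif, sd_spacer = as.integer(sd_spacer),
                 secondary_start = secondary_start,
                 atgtg_overlap = isTRUE(atgtg_overlap),
                 category = category, mode = mode),
            class = "planted_gene")
}

#' Configuration of a synthetic genome cohort
#'
#' The cohort emulates a set of conspecific bacterial genomes: a shared
#' template contig with planted regulator loci, diverged between genomes by
#' i.i.d. point substitutions. Genome index 0 (`g000`) is always emitted
#' undiverged and serves as the training genome. Identical configuration and
#' seed give byte-identical outputs.
#'
#' @param seed integer RNG seed.
#' @param n_genomes number of genomes.
#' @param contig_length contig length in nucleotides.
#' @param gc_content background GC fraction in `[0, 1]`.
#' @param genes list of [planted_gene()] specifications.
#' @param divergence_rate substitutions per site in `[0, 0.2]` applied to
#'   every genome except genome 0. Planted start/stop codons, SD motifs and
#'   secondary starts are masked from mutation (switchable via
#'   `mask_planted`), and substitutions creating an in-frame stop inside a
#'   planted ORF are reverted, emulating purifying selection.
#' @param genus_labels optional character vector (length `n_genomes`) of
#'   genus labels; default `"Escherichia"`.
#' @param species_labels optional species labels; default `"coli"`.
#' @param metadata optional data frame overriding per-genome metadata
#'   columns (`genome_id` plus any of `completeness`, `contamination`,
#'   `n_contigs`, `genome_size`); defaults are 100/0/1/contig length.
#' @param mask_planted mask planted signals from divergence (default TRUE).
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(seed, n_genomes, contig_length = 20000L,
                              gc_content = 0.5, genes, divergence_rate = 0,
                              genus_labels = NULL, species_labels = NULL,
                              metadata = NULL, mask_planted = TRUE) {
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0,1]", call. = FALSE)
  if (divergence_rate < 0 || divergence_rate > 0.2) {
    stop("divergence_rate must be in [0, 0.2]", call. = FALSE)
  }
  if (inherits(genes, "planted_gene")) genes <- list(genes)
  stopifnot(length(genes) >= 1, all(vapply(genes, inherits, TRUE, "planted_gene")))
  nms <- vapply(genes, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate gene names", call. = FALSE)
  for (g in genes) {
    if (!length(g$start_codon) %in% c(1L, n_genomes)) {
      stop("start_codon of '", g$name, "' must have length 1 or n_genomes",
           call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 contig_length = as.integer(contig_length),
                 gc_content = gc_content, genes = genes,
                 divergence_rate = divergence_rate,
                 genus_labels = genus_labels, species_labels = species_labels,
                 metadata = metadata, mask_planted = isTRUE(mask_planted)),
            class = "sim_config")
}

# Build one gene locus in gene-sense orientation.
# Returns list(block, start_in_block, stop_in_block, upstream_len, masked,
#              protected_from, secondary_in_block)
# `masked` are 0-based block offsets protected from divergence.
build_locus <- function(gene) {
  up_len <- max(30L, gene$sd_spacer + nchar(gene$sd_motif) + 12L)
  down_len <- 6L
  n_inner <- gene$orf_length / 3L - 2L  # codons between start and stop
  upstream <- paste(sample(c("A", "C", "G", "T"), up_len, replace = TRUE),
                    collapse = "")
  inner <- sample(NON_STOP_CODONS, n_inner, replace = TRUE)
  if (gene$atgtg_overlap) {
    # second ORF codon starts with A so the out-of-frame ATG reads ...TGA
    a_codons <- NON_STOP_CODONS[substr(NON_STOP_CODONS, 1, 1) == "A"]
    inner[1] <- sample(a_codons, 1L)
  }
  orf <- paste0(gene$start_codon[1], paste(inner, collapse = ""), "TAA")
  downstream <- paste(sample(c("A", "C", "G", "T"), down_len, replace = TRUE),
                      collapse = "")
  block <- paste0(upstream, orf, downstream)
  start <- up_len                       # 0-based offset of start codon
  stop_pos <- up_len + gene$orf_length - 3L
  masked <- c(start + 0:2, stop_pos + 0:2)
  # plant the SD motif ending sd_spacer nt before the start codon
  sd_len <- nchar(gene$sd_motif)
  sd_from <- start - gene$sd_spacer - sd_len  # 0-based
  if (sd_from < 0) {
    stop("sd_spacer places the motif outside the locus for gene '",
         gene$name, "'", call. = FALSE)
  }
  substr(block, sd_from + 1L, sd_from + sd_len) <- gene$sd_motif
  masked <- c(masked, sd_from + seq_len(sd_len) - 1L)
  if (gene$atgtg_overlap) {
    substr(block, start - 1L, start) <- "AT"  # positions start-2, start-1
    masked <- c(masked, start - 2L, start - 1L, start + 3L)
  }
  protected_from <- start  # earliest in-frame position kept stop-free
  sec_pos <- NA_integer_
  if (!is.null(gene$secondary_start)) {
    off <- gene$secondary_start$offset
    sec_pos <- start + off
    substr(block, sec_pos + 1L, sec_pos + 3L) <- gene$secondary_start$codon
    masked <- c(masked, sec_pos + 0:2)
    if (off < 0) {
      # keep the short stretch between the two starts free of in-frame stops
      gap_cods <- seq(sec_pos + 3L, start - 1L, by = 3L)
      for (p in gap_cods[gap_cods + 2L < start]) {
        if (codon_at(block, p) %in% STOP_CODONS) {
          substr(block, p + 1L, p + 3L) <- sample(NON_STOP_CODONS, 1L)
        }
      }
      protected_from <- sec_pos
    }
  }
  list(block = block, start = start, stop_pos = stop_pos,
       up_len = up_len, masked = sort(unique(masked)),
       protected_from = protected_from, secondary = sec_pos)
}

#' Generate a synthetic genome cohort with planted regulator loci
#'
#' Builds a background contig at the configured GC content, plants every
#' gene once at a recorded location, then derives each non-training genome
#' by i.i.d. point substitutions at `divergence_rate` (planted signals
#' masked; nonsense substitutions inside planted ORFs reverted). Genome 0 is
#' emitted undiverged together with a GFF3-style annotation of its planted
#' genes, usable to train the start model.
#'
#' @param config a [simulation_config()].
#' @return an object of class `sim_cohort`: a list with `genomes` (named
#'   list; each genome a named character vector of contigs), `annotation`
#'   (data frame for genome 0), `metadata`, `manifest` and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    gc <- config$gc_content
    base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    loci <- lapply(config$genes, build_locus)
    blocks <- vapply(loci, function(l) nchar(l$block), 0)
    gaps <- sample(50:150, length(loci), replace = TRUE)
    total_needed <- sum(blocks) + sum(gaps) + 100L
    if (total_needed > config$contig_length) {
      stop("contig_length ", config$contig_length, " too small for planted ",
           "loci (need >= ", total_needed, ")", call. = FALSE)
    }
    template <- sample(names(base_probs), config$contig_length,
                       replace = TRUE, prob = base_probs)
    # sequential placement with random gaps, extra slack appended at the end
    offsets <- integer(length(loci))
    pos <- 50L
    for (i in seq_along(loci)) {
      pos <- pos + gaps[i]
      offsets[i] <- pos
      pos <- pos + blocks[i]
    }
    manifest <- list()
    masked_fwd <- integer(0)
    orf_ranges <- list()  # per gene: forward-strand info for stop repair
    for (i in seq_along(loci)) {
      l <- loci[[i]]
      g <- config$genes[[i]]
      b <- offsets[i]
      blk <- dna_chars(l$block)
      fwd_start <- if (g$strand == "+") b + l$start else
        b + (blocks[i] - l$start - 3L)
      if (g$strand == "-") blk <- dna_chars(revcomp(l$block))
      template[(b + 1L):(b + blocks[i])] <- blk
      mk <- if (g$strand == "+") b + l$masked else b + (blocks[i] - l$masked - 1L)
      masked_fwd <- c(masked_fwd, mk)
      sec_fwd <- if (is.na(l$secondary)) NA_integer_ else if (g$strand == "+")
        b + l$secondary else b + (blocks[i] - l$secondary - 3L)
      manifest[[i]] <- data.frame(
        gene = g$name, contig_id = NA_character_,
        pos = fwd_start, strand = g$strand, codon = g$start_codon[1],
        spacer = g$sd_spacer, orf_length = g$orf_length,
        secondary_pos = sec_fwd,
        secondary_codon = if (is.null(g$secondary_start)) NA_character_ else
          g$secondary_start$codon,
        category = g$category, mode = g$mode, stringsAsFactors = FALSE)
      orf_ranges[[i]] <- list(block_from = b, block_len = blocks[i],
                              strand = g$strand,
                              gs_from = l$protected_from, gs_to = l$stop_pos)
    }
    genome_ids <- sprintf("g%03d", seq_len(config$n_genomes) - 1L)
    contig_ids <- paste0(genome_ids, "_c1")
    genomes <- vector("list", config$n_genomes)
    names(genomes) <- genome_ids
    manifest_all <- list()
    for (gi in seq_len(config$n_genomes)) {
      chars <- template
      man <- do.call(rbind, manifest)
      # per-genome start codon overrides
      for (i in seq_along(config$genes)) {
        g <- config$genes[[i]]
        if (length(g$start_codon) > 1L) {
          codon <- g$start_codon[gi]
          man$codon[i] <- codon
          p <- man$pos[i]
          tri <- if (g$strand == "+") codon else revcomp(codon)
          chars[(p + 1L):(p + 3L)] <- dna_chars(tri)
        }
      }
      if (gi > 1L && config$divergence_rate > 0) {
        hit <- which(runif(length(chars)) < config$divergence_rate)
        if (config$mask_planted) hit <- setdiff(hit, masked_fwd + 1L)
        if (length(hit) > 0) {
          repl <- vapply(chars[hit], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, "")
          chars[hit] <- repl
          # purifying selection: revert substitutions creating in-frame stops
          for (r in orf_ranges) {
            blk <- chars[(r$block_from + 1L):(r$block_from + r$block_len)]
            gs <- if (r$strand == "+") blk else dna_chars(revcomp(paste(blk, collapse = "")))
            tmpl_blk <- template[(r$block_from + 1L):(r$block_from + r$block_len)]
            gs_t <- if (r$strand == "+") tmpl_blk else
              dna_chars(revcomp(paste(tmpl_blk, collapse = "")))
            for (p in seq(r$gs_from, r$gs_to - 3L, by = 3L)) {
              cod <- paste(gs[(p + 1L):(p + 3L)], collapse = "")
              if (cod %in% STOP_CODONS) gs[(p + 1L):(p + 3L)] <- gs_t[(p + 1L):(p + 3L)]
            }
            blk2 <- if (r$strand == "+") gs else dna_chars(revcomp(paste(gs, collapse = "")))
            chars[(r$block_from + 1L):(r$block_from + r$block_len)] <- blk2
          }
        }
      }
      contig <- paste(chars, collapse = "")
      genomes[[gi]] <- stats::setNames(contig, contig_ids[gi])
      man$contig_id <- contig_ids[gi]
      man <- cbind(genome_id = genome_ids[gi], man, stringsAsFactors = FALSE)
      manifest_all[[gi]] <- man
    }
    manifest_df <- do.call(rbind, manifest_all)
    rownames(manifest_df) <- NULL
    # sanity: recorded codon present at recorded position/strand
    for (r in seq_len(nrow(manifest_df))) {
      m <- manifest_df[r, ]
      tri <- codon_at(genomes[[m$genome_id]][[1]], m$pos)
      if (m$strand == "-") tri <- revcomp(tri)
      stopifnot(tri == m$codon)
    }
    metadata <- data.frame(
      genome_id = genome_ids,
      genus = config$genus_labels %||% rep("Escherichia", config$n_genomes),
      species = config$species_labels %||% rep("coli", config$n_genomes),
      completeness = 100, contamination = 0, n_contigs = 1L,
      genome_size = config$contig_length, stringsAsFactors = FALSE)
    if (!is.null(config$metadata)) {
      ov <- config$metadata
      idx <- match(ov$genome_id, metadata$genome_id)
      for (cl in setdiff(colnames(ov), "genome_id")) {
        metadata[[cl]][idx] <- ov[[cl]]
      }
    }
    ann <- manifest_df[manifest_df$genome_id == genome_ids[1], ]
    annotation <- data.frame(
      seqid = ann$contig_id,
      start = ifelse(ann$strand == "+", ann$pos + 1L,
                     ann$pos + 3L - ann$orf_length + 1L),
      end = ifelse(ann$strand == "+", ann$pos + ann$orf_length, ann$pos + 3L),
      strand = ann$strand, name = ann$gene, stringsAsFactors = FALSE)
    structure(list(genomes = genomes, annotation = annotation,
                   metadata = metadata, manifest = manifest_df,
                   config = config),
              class = "sim_cohort")
  })
}

#' Extract reference gene sequences from a cohort's training genome
#'
#' Returns the planted ORF sequences of genome 0 in gene-sense orientation,
#' with category and mode labels, ready to use as homology queries.
#'
#' @param cohort a `sim_cohort`.
#' @return a data frame with columns `name`, `sequence`, `category`, `mode`.
#' @export
cohort_references <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  g0 <- names(cohort$genomes)[1]
  man <- cohort$manifest[cohort$manifest$genome_id == g0, ]
  contig <- cohort$genomes[[g0]][[1]]
  seqs <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    m <- man[i, ]
    if (m$strand == "+") {
      seqs[i] <- substr(contig, m$pos + 1L, m$pos + m$orf_length)
    } else {
      seqs[i] <- revcomp(substr(contig, m$pos + 3L - m$orf_length + 1L, m$pos + 3L))
    }
  }
  reference_genes(man$gene, seqs, man$category, man$mode)
}

#' Construct a reference gene table
#'
#' @param name gene symbols.
#' @param sequence nucleotide sequences (>= 90 nt, alphabet `A/C/G/T/N`).
#' @param category `"carbohydrate"` or `"non-carbohydrate"` per gene.
#' @param mode `"positive"`, `"negative"` or `"bidirectional"` per gene.
#' @return a data frame of class `reference_genes`.
#' @export
reference_genes <- function(name, sequence,
                            category = "carbohydrate", mode = "negative") {
  sequence <- vapply(sequence, check_dna, "", what = "reference sequence")
  if (any(nchar(sequence) < 90)) {
    stop("reference sequences must be at least 90 nt", call. = FALSE)
  }
  out <- data.frame(name = name, sequence = unname(sequence),
                    category = category, mode = mode, stringsAsFactors = FALSE)
  class(out) <- c("reference_genes", "data.frame")
  out
}

#' Write cohort artifacts to disk
#'
#' Emits one FASTA per genome (70-column wrap), a GFF3 annotation of the
#' training genome, and TSV metadata/manifest tables. Identical cohorts give
#' byte-identical files.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(cohort$genomes)) {
    p <- file.path(gdir, paste0(id, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(cohort$genomes[[id]]), p, width = 70L)
    paths <- c(paths, p)
  }
  gff <- file.path(dir, "training.gff3")
  ann <- cohort$annotation
  gr <- GenomicRanges::GRanges(
    seqnames = ann$seqid,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand, type = "gene",
    ID = paste0("gene", seq_len(nrow(ann))), Name = ann$name)
  rtracklayer::export(gr, gff, format = "gff3")
  meta <- file.path(dir, "metadata.tsv")
  write.table(cohort$metadata, meta, sep = "\t", quote = FALSE,
              row.names = FALSE)
  man <- file.path(dir, "manifest.tsv")
  write.table(cohort$manifest, man, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, gff, meta, man))
}
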