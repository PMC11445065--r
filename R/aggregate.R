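#' Quality-control filter on genome metadata
#'
#' Keeps genomes with completeness >= `min_completeness`, contamination not
#' larger than `max_contamination` (the rule excludes values strictly above
#' the threshold), at most `max_contigs` contigs, and genome size no smaller
#' than the species median minus 3 scaled MADs. Every exclusion is logged
#' with all the rules it failed.
#'
#' @param metadata data frame with columns `genome_id`, `species`,
#'   `completeness`, `contamination`, `n_contigs`, `genome_size`.
#' @param min_completeness minimum completeness percent (default 95).
#' @param max_contamination maximum contamination percent (default 10).
#' @param max_contigs maximum contig count (default 200).
#' @param size_rule apply the species-median size rule (default TRUE).
#' @return list with `kept` (genome ids) and `log` (data frame `genome_id`,
#'   `reasons`).
#' @export
qc_filter <- function(metadata, min_completeness = 95,
                      max_contamination = 10, max_contigs = 200L,
                      size_rule = TRUE) {
  need <- c("genome_id", "species", "completeness", "contamination",
            "n_contigs", "genome_size")
  miss <- setdiff(need, colnames(metadata))
  if (length(miss) > 0) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  reasons <- vector("list", nrow(metadata))
  fail <- function(i, why) reasons[[i]] <<- c(reasons[[i]], why)
  size_floor <- stats::ave(metadata$genome_size, metadata$species,
                           FUN = function(x) median(x) - 3 * mad(x))
  for (i in seq_len(nrow(metadata))) {
    if (metadata$completeness[i] < min_completeness) fail(i, "completeness")
    if (metadata$contamination[i] > max_contamination) fail(i, "contamination")
    if (metadata$n_contigs[i] > max_contigs) fail(i, "n_contigs")
    if (size_rule && metadata$genome_size[i] < size_floor[i]) fail(i, "genome_size")
  }
  excluded <- which(lengths(reasons) > 0)
  list(kept = metadata$genome_id[setdiff(seq_len(nrow(metadata)), excluded)],
       log = data.frame(
         genome_id = metadata$genome_id[excluded],
         reasons = vapply(reasons[excluded], paste, "", collapse = ";"),
         stringsAsFactors = FALSE))
}

#' Genus-level subsampling of a genome cohort
#'
#' Genera with fewer than `min_per_genus` genomes are discarded entirely;
#' genera with more than `max_per_genus` are uniformly subsampled without
#' replacement to exactly `max_per_genus`. Deterministic for a given seed
#' (genera are processed in sorted order).
#'
#' @param metadata data frame with `genome_id` and `genus` columns.
#' @param max_per_genus cap per genus (default 100).
#' @param min_per_genus minimum genus size (default 10).
#' @param seed integer RNG seed.
#' @return character vector of kept genome ids.
#' @export
subsample_genera <- function(metadata, max_per_genus = 100L,
                             min_per_genus = 10L, seed = 1L) {
  stopifnot(all(c("genome_id", "genus") %in% colnames(metadata)))
  with_seed(seed, {
    kept <- character(0)
    for (g in sort(unique(metadata$genus))) {
      ids <- metadata$genome_id[metadata$genus == g]
      if (length(ids) < min_per_genus) next
      if (length(ids) > max_per_genus) ids <- sort(sample(ids, max_per_genus))
      kept <- c(kept, ids)
    }
    kept
  })
}

#' Aggregate fractional start-codon calls into usage percentages
#'
#' Per gene (optionally per gene x genus), the percentage of each codon
#' class is 100 times the mean of the per-genome fractions over genomes
#' contributing a non-flagged call; each genome contributes equally.
#' Alongside the fraction-weighted percentages, a majority-call percentage
#' (`majority_non_atg_percent`, the share of genomes whose single largest
#' weight is non-ATG) is reported.
#'
#' @param records calls data frame with columns `genome_id`, `gene`, `ATG`,
#'   `GTG`, `TTG`, `other` (fractions summing to 1, or all zero when
#'   flagged).
#' @param metadata optional metadata with `genome_id`, `genus`; required
#'   when `by_genus = TRUE`. When supplied, records are restricted to
#'   genomes present in it.
#' @param by_genus aggregate per gene x genus instead of per gene.
#' @return a `usage_summary` data frame: grouping columns, `n_genomes`,
#'   `pct_ATG`, `pct_GTG`, `pct_TTG`, `pct_other`, `non_atg_percent`,
#'   `majority_non_atg_percent`.
#' @export
aggregate_usage <- function(records, metadata = NULL, by_genus = FALSE) {
  fr <- as.matrix(records[, CODON_CLASSES])
  sums <- rowSums(fr)
  ok <- abs(sums - 1) < 1e-9
  if (any(!ok & sums != 0)) {
    stop("usage fractions must sum to 1 or be all zero (flagged)", call. = FALSE)
  }
  if (!is.null(metadata)) {
    if (!all(records$genome_id %in% metadata$genome_id)) {
      stop("records contain genomes absent from metadata", call. = FALSE)
    }
  }
  recs <- records[ok, , drop = FALSE]
  dropped <- unique(records$gene[!records$gene %in% recs$gene])
  if (length(dropped) > 0) {
    message("gene(s) with zero contributing genomes omitted: ",
            paste(dropped, collapse = ", "))
  }
  if (by_genus) {
    if (is.null(metadata)) stop("by_genus requires metadata", call. = FALSE)
    recs$genus <- metadata$genus[match(recs$genome_id, metadata$genome_id)]
    grp <- interaction(recs$gene, recs$genus, drop = TRUE)
  } else {
    grp <- factor(recs$gene)
  }
  rows <- lapply(levels(grp), function(gv) {
    sub <- recs[grp == gv, , drop = FALSE]
    m <- colMeans(as.matrix(sub[, CODON_CLASSES]))
    maj <- CODON_CLASSES[max.col(as.matrix(sub[, CODON_CLASSES]),
                                 ties.method = "first")]
    out <- data.frame(gene = sub$gene[1], stringsAsFactors = FALSE)
    if (by_genus) out$genus <- sub$genus[1]
    out$n_genomes <- nrow(sub)
    out$pct_ATG <- 100 * m[["ATG"]]
    out$pct_GTG <- 100 * m[["GTG"]]
    out$pct_TTG <- 100 * m[["TTG"]]
    out$pct_other <- 100 * m[["other"]]
    out$non_atg_percent <- 100 - out$pct_ATG
    out$majority_non_atg_percent <- 100 * mean(maj != "ATG")
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("usage_summary", "data.frame")
  res
}

#' Compare non-ATG usage between regulator categories
#'
#' Splits per-regulator non-ATG percentages by category (carbohydrate vs
#' non-carbohydrate) and applies the two-tailed Mann-Whitney U test; when
#' regulatory modes are available, the same comparison is emitted per mode
#' (positive / negative / bidirectional).
#'
#' @param summary a `usage_summary` from [aggregate_usage()] (per gene).
#' @param references a [reference_genes()] data frame or any data frame
#'   with `name`, `category` and optionally `mode` columns.
#' @return data frame with one row per comparison: `subset`, `n_carb`,
#'   `n_noncarb`, `median_carb`, `median_noncarb`, `U`, `p`, `band`.
#' @export
compare_categories <- function(summary, references) {
  cat_map <- references$category[match(summary$gene, references$name)]
  if (anyNA(cat_map)) {
    stop("gene(s) without a category: ",
         paste(summary$gene[is.na(cat_map)], collapse = ", "), call. = FALSE)
  }
  mode_map <- if ("mode" %in% colnames(references)) {
    references$mode[match(summary$gene, references$name)]
  } else rep(NA_character_, nrow(summary))
  one <- function(subset_name, sel) {
    x <- summary$non_atg_percent[sel & cat_map == "carbohydrate"]
    y <- summary$non_atg_percent[sel & cat_map != "carbohydrate"]
    if (length(x) == 0 || length(y) == 0) return(NULL)
    mw <- mann_whitney_u(x, y)
    data.frame(subset = subset_name, n_carb = length(x), n_noncarb = length(y),
               median_carb = median(x), median_noncarb = median(y),
               U = mw$statistic, p = mw$p.value,
               band = significance_band(mw$p.value), stringsAsFactors = FALSE)
  }
  rows <- list(one("all", rep(TRUE, nrow(summary))))
  for (m in sort(unique(stats::na.omit(mode_map)))) {
    rows[[length(rows) + 1L]] <- one(m, !is.na(mode_map) & mode_map == m)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
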