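#' @useDynLib startcall, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median mad pnorm rnorm runif
#' @importFrom utils combn write.table read.delim
"_PACKAGE"

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")
CODON_CLASSES <- c("ATG", "GTG", "TTG", "other")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements (upper case).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' Truncate (not round) to two decimal places
#'
#' Human-readable start-codon fractions are reported truncated to two
#' decimals, so 2/3 prints as 0.66 and 1/3 as 0.33. A 1e-9 guard absorbs
#' representation error in values that are exact two-decimal fractions.
#'
#' @param x numeric vector.
#' @return numeric vector truncated to two decimals.
#' @export
trunc2 <- function(x) {
  floor(x * 100 + 1e-9) / 100
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Validate a DNA string; returns the upper-cased sequence or errors naming
# the first offending symbol.
check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty DNA string", call. = FALSE)
  }
  x <- toupper(x)
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad) > 0) {
    stop(what, " contains symbol(s) outside {", paste(alphabet, collapse = ","),
         "}: '", paste(bad, collapse = "','"), "'", call. = FALSE)
  }
  x
}

# Split a DNA string into a character vector of single bases.
dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Extract the codon at 0-based position `pos` of string `x`.
codon_at <- function(x, pos) substr(x, pos + 1L, pos + 3L)

`%||%` <- function(a, b) if (is.null(a)) b else a
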