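#' Two-tailed Mann-Whitney U test
#'
#' U is computed from midrank sums. The two-tailed p-value is exact by
#' complete enumeration of rank assignments when `n1 + n2 <= 12` and there
#' are no ties, and otherwise uses the normal approximation with tie
#' correction and continuity correction. Swapping the groups maps U to
#' `n1 * n2 - U` and leaves p unchanged.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `statistic` (U for `x`), `p.value` and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  mu <- n1 * n2 / 2
  if (!ties && n1 + n2 <= 12) {
    # exact: U is distribution-free given ranks; enumerate group assignments
    N <- n1 + n2
    combos <- combn(N, n1)
    us <- apply(combos, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  N <- n1 + n2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(statistic = U, p.value = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- min(1, 2 * pnorm(-z))
  list(statistic = U, p.value = p, method = "normal")
}

#' Significance band used in figure legends
#'
#' `NS` for p >= 0.05, then `*` (< 0.05), `**` (< 0.01), `***` (< 0.001).
#'
#' @param p numeric p-value(s).
#' @return character vector of bands.
#' @export
significance_band <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS")))
}
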