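#' Two-sided p-value for a Pearson correlation
#'
#' Student-t transform of a correlation coefficient: `t = r sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom, two-sided. Vectorized over `r`.
#'
#' @param r correlation coefficient(s) in `[-1, 1]`.
#' @param n number of paired observations (must be >= 3).
#' @return numeric vector of two-sided p-values; `|r| = 1` maps to 0.
#' @export
cor_pvalue <- function(r, n) {
  stopifnot(n >= 3)
  r <- pmin(1, pmax(-1, r))
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(t, df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' 1 = identical partitions (up to label renaming), ~0 = chance agreement.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Standardize matrix rows to zero mean, unit variance
#' @noRd
scale_rows <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1L, sd)
  (x - m) / s
}

stop_coex <- function(msg, class = "coexmod_error") {
  abort(msg, class = class)
}
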