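#' Enumerate all sample bipartitions
#'
#' Every unordered split of `n` samples into two non-empty groups, each
#' exactly once: `2^(n-1) - 1` splits. Canonical form fixes sample 1 in
#' group 0, so a split and its complement are never both produced.
#'
#' @param n number of samples, `2 <= n <= 25`.
#' @return a 0/1 integer matrix, one column per bipartition (n x
#'   `2^(n-1) - 1`); row 1 is all zero.
#' @export
enumerate_bipartitions <- function(n) {
  if (n < 2 || n > 25) stop_coex("n must be between 2 and 25")
  m <- 2^(n - 1) - 1
  # bit b of code j = group of sample b+2; sample 1 pinned to group 0
  codes <- seq_len(m)
  out <- matrix(0L, nrow = n, ncol = m)
  for (b in seq_len(n - 1)) {
    out[b + 1L, ] <- bitwAnd(bitwShiftR(codes, b - 1L), 1L)
  }
  out
}

#' Exhaustive bipartition scan of module eigengenes
#'
#' Tests every bipartition of the samples against every module eigengene:
#' Pearson correlation of the eigengene with the 0/1 group indicator,
#' two-sided t-test on `n - 2` df, Bonferroni correction over all tests.
#' Used to detect an unrecorded binary covariate (e.g. embryo sex) that a
#' module might actually track.
#'
#' @param modules a `coex_modules`/`coex_me` object or eigengene matrix
#'   (modules x samples).
#' @param alpha significance level on the adjusted p-value (default 0.01).
#' @param family Bonferroni family: `"partitions_x_modules"` (default) or
#'   `"partitions"` only.
#' @param partitions optional precomputed indicator matrix from
#'   [enumerate_bipartitions()] (useful when scanning many eigengene sets of
#'   the same sample size, e.g. in null simulations).
#' @return a `coex_scan` object; its `table` has one row per module with the
#'   best partition (as a 0/1 bitstring), raw and adjusted p, and a flag.
#' @export
scan_partitions <- function(modules, alpha = 0.01,
                            family = c("partitions_x_modules", "partitions"),
                            partitions = NULL) {
  family <- match.arg(family)
  me <- extract_me(modules)
  n <- ncol(me)
  if (n < 4) stop_coex("need >= 4 samples")
  parts <- if (is.null(partitions)) enumerate_bipartitions(n) else partitions
  if (nrow(parts) != n) stop_coex("partitions do not match the sample count")
  n_parts <- ncol(parts)
  multiplier <- if (family == "partitions_x_modules") {
    n_parts * nrow(me)
  } else {
    n_parts
  }
  # r for all module x partition pairs in one crossprod of standardized forms
  me_s <- me - rowMeans(me)
  me_s <- me_s / sqrt(rowSums(me_s^2))
  p_s <- parts - rep(colMeans(parts), each = n)
  p_s <- p_s / rep(sqrt(colSums(p_s^2)), each = n)
  r_all <- me_s %*% p_s  # modules x partitions
  best <- max.col(abs(r_all), ties.method = "first")
  r_best <- r_all[cbind(seq_len(nrow(me)), best)]
  p_raw <- cor_pvalue(r_best, n)
  p_adj <- pmin(1, p_raw * multiplier)
  tab <- tibble(
    module = rownames(me) %||% paste0("ME", seq_len(nrow(me))),
    best_partition = vapply(best, function(j)
      paste(parts[, j], collapse = ""), character(1)),
    r = r_best, p = p_raw, p_adj = p_adj,
    flagged = p_adj < alpha,
    n_partitions = n_parts, multiplier = multiplier
  )
  structure(list(table = tab, alpha = alpha, family = family,
                 n_partitions = n_parts, multiplier = multiplier),
            class = "coex_scan")
}

#' @export
print.coex_scan <- function(x, ...) {
  cat("<coex_scan> ", nrow(x$table), " modules x ", x$n_partitions,
      " bipartitions (Bonferroni multiplier ", x$multiplier, ")\n", sep = "")
  flg <- x$table$module[x$table$flagged]
  cat("  flagged at alpha = ", x$alpha, ": ",
      if (length(flg)) paste(flg, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}
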