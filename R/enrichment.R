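#' Over-representation analysis by the hypergeometric test
#'
#' One-sided hypergeometric tail p per term for over-representation of the
#' term among `test_set` relative to `universe`, Benjamini-Hochberg adjusted
#' across terms. Terms with no annotated universe gene are skipped.
#'
#' @param test_set character vector of genes of interest (subset of
#'   `universe`).
#' @param universe character vector: the reference gene set.
#' @param annot data frame with columns `gene` and `term` (one row per
#'   annotation); genes outside the universe are ignored.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return a `coex_enrich` object; its `table` has term, test/universe
#'   counts, expected count, fold enrichment, p, p_adj, significant.
#' @export
overrepresentation <- function(test_set, universe, annot, alpha = 0.05) {
  test_set <- unique(as.character(test_set))
  universe <- unique(as.character(universe))
  if (!length(test_set)) stop_coex("test set is empty")
  if (!all(test_set %in% universe)) {
    stop_coex("test_set must be a subset of universe")
  }
  annot <- as_tibble(annot)
  stopifnot(all(c("gene", "term") %in% names(annot)))
  annot <- annot[annot$gene %in% universe, c("gene", "term")]
  annot <- unique(annot)
  N <- length(universe)
  k <- length(test_set)
  per_term <- annot |>
    group_by(.data$term) |>
    summarise(universe_count = dplyr::n_distinct(.data$gene),
              test_count = sum(unique(.data$gene) %in% test_set),
              .groups = "drop") |>
    filter(.data$universe_count > 0)
  if (!nrow(per_term)) stop_coex("no term annotates the universe")
  p <- phyper(per_term$test_count - 1, per_term$universe_count,
              N - per_term$universe_count, k, lower.tail = FALSE)
  expected <- k * per_term$universe_count / N
  tab <- per_term |>
    mutate(expected = expected,
           fold = .data$test_count / expected,
           p = p,
           p_adj = p.adjust(p, method = "BH"),
           significant = .data$p_adj < alpha) |>
    arrange(.data$p)
  structure(list(table = tab, n_universe = N, n_test = k, alpha = alpha,
                 method = "hypergeometric"),
            class = "coex_enrich")
}

#' @export
print.coex_enrich <- function(x, ...) {
  cat("<coex_enrich> ", nrow(x$table), " terms (", x$method, "), ",
      sum(x$table$significant), " significant at BH ", x$alpha, "\n",
      sep = "")
  invisible(x)
}

#' Length-bias selection weights
#'
#' Estimates a monotone probability-weighting function P(selected | length)
#' by binning genes on length and pool-adjacent-violators (isotonic)
#' regression of the per-bin selection fraction, in the direction of the
#' observed trend. Used to feed the Wallenius test.
#'
#' @param de_flags logical/0-1 vector: selected gene per universe gene.
#' @param lengths positive gene lengths (bp), same order.
#' @param n_bins number of equal-occupancy length bins (default 10, reduced
#'   for small universes).
#' @return numeric weight per gene, bounded away from zero.
#' @export
length_bias_weights <- function(de_flags, lengths, n_bins = 10) {
  de_flags <- as.numeric(de_flags)
  stopifnot(length(de_flags) == length(lengths), all(lengths > 0))
  if (all(de_flags == 1) || all(de_flags == 0)) {
    stop_coex("selection must be neither empty nor the whole universe")
  }
  n_bins <- max(2L, min(n_bins, floor(length(lengths) / 5)))
  ord <- order(lengths)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  frac <- tapply(de_flags[ord], bin, mean)
  mid <- tapply(lengths[ord], bin, mean)
  if (diff(range(mid)) < sqrt(.Machine$double.eps)) {
    # no length spread: selection cannot depend on length
    return(rep(max(mean(de_flags), 1e-6), length(lengths)))
  }
  increasing <- cor(seq_along(frac), frac) >= 0
  fit <- if (increasing) isoreg(frac)$yf else -isoreg(-frac)$yf
  w <- approx(mid, fit, xout = lengths, rule = 2)$y
  pmax(w, 1e-6)
}

# Wallenius noncentral hypergeometric log-pmf over the support, by numeric
# integration of (1 - t^(w/D))^x (1 - t^(1/D))^(n-x) on (0, 1).
wallenius_logpmf <- function(m1, m2, n, omega) {
  supp <- max(0, n - m2):min(n, m1)
  lp <- vapply(supp, function(x) {
    D <- omega * (m1 - x) + (m2 - (n - x))
    if (D <= 0) D <- .Machine$double.eps
    f <- function(t) (1 - t^(omega / D))^x * (1 - t^(1 / D))^(n - x)
    I <- integrate(f, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
    lchoose(m1, x) + lchoose(m2, n - x) + log(max(I, .Machine$double.xmin))
  }, numeric(1))
  # normalize: the integral representation is exact but renormalizing absorbs
  # quadrature error
  lse <- max(lp) + log(sum(exp(lp - max(lp))))
  list(support = supp, logpmf = lp - lse)
}

#' Wallenius over-representation test with length-bias correction
#'
#' Like [overrepresentation()], but the null accounts for length-biased
#' selection: genes are drawn with odds proportional to their length-bias
#' weight, so a term whose genes are long is not called enriched merely
#' because long genes are more detectable. Per term the odds ratio is the
#' mean weight inside the term over the mean weight outside, and the
#' one-sided p comes from the Wallenius noncentral hypergeometric
#' distribution.
#'
#' @inheritParams overrepresentation
#' @param lengths positive lengths (bp) named by universe gene, or in
#'   universe order.
#' @param n_bins passed to [length_bias_weights()].
#' @return a `coex_enrich` object (method `"wallenius"`) whose `table` also
#'   carries the per-term odds ratio.
#' @export
wallenius_test <- function(test_set, universe, annot, lengths,
                           alpha = 0.05, n_bins = 10) {
  test_set <- unique(as.character(test_set))
  universe <- unique(as.character(universe))
  if (!length(test_set)) stop_coex("test set is empty")
  if (!all(test_set %in% universe)) {
    stop_coex("test_set must be a subset of universe")
  }
  if (!is.null(names(lengths))) lengths <- lengths[universe]
  stopifnot(length(lengths) == length(universe))
  de <- universe %in% test_set
  w <- length_bias_weights(de, lengths, n_bins = n_bins)
  names(w) <- universe
  annot <- unique(as_tibble(annot)[, c("gene", "term")])
  annot <- annot[annot$gene %in% universe, ]
  per_term <- annot |>
    group_by(.data$term) |>
    summarise(genes = list(unique(.data$gene)), .groups = "drop") |>
    mutate(universe_count = map_int(.data$genes, length)) |>
    filter(.data$universe_count > 0)
  if (!nrow(per_term)) stop_coex("no term annotates the universe")
  n_test <- length(test_set)
  N <- length(universe)
  res <- map(per_term$genes, function(g) {
    m1 <- length(g)
    x <- sum(g %in% test_set)
    inside <- mean(w[g])
    outside <- mean(w[setdiff(universe, g)])
    omega <- inside / outside
    pm <- wallenius_logpmf(m1, N - m1, n_test, omega)
    tail <- pm$logpmf[pm$support >= x]
    p <- if (length(tail)) min(1, sum(exp(tail))) else 0
    tibble(test_count = x, odds = omega, p = max(p, .Machine$double.xmin))
  })
  tab <- bind_rows(res) |>
    mutate(term = per_term$term, universe_count = per_term$universe_count,
           .before = 1) |>
    mutate(p_adj = p.adjust(.data$p, method = "BH"),
           significant = .data$p_adj < alpha) |>
    arrange(.data$p)
  structure(list(table = tab, n_universe = N, n_test = n_test, alpha = alpha,
                 method = "wallenius", weights = w),
            class = "coex_enrich")
}

#' Roll significant terms up to slim categories
#'
#' Tallies the significant terms of an enrichment result into broad (GOSlim
#' style) categories; terms missing from the map land in `"other"`.
#'
#' @param result a `coex_enrich` object.
#' @param slim_map data frame with columns `term` and `category`.
#' @return a tibble with `category` and `n_significant`, including
#'   zero-count categories present in the map.
#' @export
slim_rollup <- function(result, slim_map) {
  stopifnot(inherits(result, "coex_enrich"))
  slim_map <- unique(as_tibble(slim_map)[, c("term", "category")])
  sig <- result$table$term[result$table$significant]
  cat_of <- setNames(slim_map$category, slim_map$term)
  assigned <- ifelse(sig %in% names(cat_of), cat_of[sig], "other")
  cats <- sort(unique(slim_map$category))
  out <- tibble(category = c(cats, "other")) |>
    mutate(n_significant = map_int(.data$category,
                                   function(cc) sum(assigned == cc)))
  if (!any(assigned == "other")) out <- out[out$category != "other", ]
  out
}
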