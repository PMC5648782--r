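#' Counts per million
#'
#' `cpm_ij = counts_ij * 1e6 / libsize_j`, library size = column total.
#'
#' @param x a [coex_counts()] or a bare counts matrix.
#' @return a numeric matrix of the same shape.
#' @export
cpm_matrix <- function(x) {
  counts <- if (inherits(x, "coex_counts")) x$counts else as.matrix(x)
  tot <- colSums(counts)
  zero <- which(tot == 0)
  if (length(zero)) {
    stop_coex(paste0("zero-total sample(s): ",
                     paste(colnames(counts)[zero], collapse = ", ")))
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Reads per kilobase per million
#'
#' `rpkm_ij = counts_ij * 1e9 / (libsize_j * length_i)`.
#'
#' @param x a [coex_counts()] (gene lengths are taken from it), or a matrix
#'   together with `gene_length`.
#' @param gene_length lengths in bp when `x` is a bare matrix.
#' @return a numeric matrix of RPKM values.
#' @export
rpkm_matrix <- function(x, gene_length = NULL) {
  if (inherits(x, "coex_counts")) {
    counts <- x$counts
    gene_length <- x$gene_length
  } else {
    counts <- as.matrix(x)
  }
  if (is.null(gene_length)) stop_coex("gene lengths are required for RPKM")
  if (length(gene_length) != nrow(counts) || any(!is.finite(gene_length))) {
    bad <- rownames(counts)[which(!is.finite(gene_length))]
    stop_coex(paste0("missing gene length",
                     if (length(bad)) paste0(" for: ", paste(head(bad, 5), collapse = ", "))))
  }
  cpm_matrix(counts) * 1e3 / gene_length
}

#' Abundance filter: keep genes detected in at least one library
#'
#' Keeps a gene iff its CPM in at least one library reaches the CPM
#' equivalent of `min_count` reads in the median-depth library
#' (`min_count / median(libsize) * 1e6`), so the cutoff accounts for
#' library-size differences. The boundary is inclusive. `strict_counts = TRUE`
#' instead applies the raw rule "count >= min_count in >= 1 library".
#'
#' @param x a [coex_counts()].
#' @param min_count minimum evidence, in reads at median depth (default 5).
#' @param strict_counts use raw counts rather than CPM.
#' @return the filtered [coex_counts()] with an updated filter log.
#' @export
filter_abundance <- function(x, min_count = 5, strict_counts = FALSE) {
  stopifnot(inherits(x, "coex_counts"))
  if (min_count < 1) stop_coex("min_count must be >= 1")
  if (strict_counts) {
    keep <- apply(x$counts, 1L, max) >= min_count
  } else {
    cutoff <- min_count / median(colSums(x$counts)) * 1e6
    keep <- apply(cpm_matrix(x), 1L, max) >= cutoff
  }
  x <- append_filter_log(x, "abundance", keep,
                         list(min_count = min_count,
                              strict_counts = strict_counts))
  subset_counts(x, keep)
}

#' Variance filter on a log2 expression matrix
#'
#' Removes genes whose gene-wise variance falls below
#' `factor x overall`, where the overall statistic summarizes the gene-wise
#' variances (`mean`, `median`, or `pooled` = variance of the whole matrix).
#' Note the default `factor = 2` with `stat = "mean"` is aggressive by
#' construction: it keeps only genes at least twice as variable as the
#' average gene.
#'
#' @param values log2 expression matrix (genes x samples), or a `coex_expr`.
#' @param factor non-negative multiplier of the overall statistic.
#' @param stat one of `"mean"`, `"median"`, `"pooled"`.
#' @return object of the same type, genes failing the rule removed; a
#'   `filter_log` record is appended when the input carries one.
#' @export
filter_variance <- function(values, factor = 2.0,
                            stat = c("mean", "median", "pooled")) {
  stat <- match.arg(stat)
  if (factor < 0) stop_coex("factor must be non-negative")
  is_expr <- inherits(values, "coex_expr")
  m <- if (is_expr) values$values else as.matrix(values)
  if (ncol(m) < 3) stop_coex("variance filtering needs >= 3 samples")
  v <- apply(m, 1L, var)
  overall <- switch(stat, mean = mean(v), median = median(v),
                    pooled = var(as.vector(m)))
  keep <- v >= factor * overall
  if (is_expr) {
    values$values <- m[keep, , drop = FALSE]
    rec <- list(step = "variance", n_before = length(keep),
                n_removed = sum(!keep), n_after = sum(keep),
                params = list(factor = factor, stat = stat))
    values$filter_log <- c(values$filter_log, list(rec))
    values
  } else {
    m[keep, , drop = FALSE]
  }
}

# Literal TMM recipe is delegated to edgeR (calcNormFactors, method "TMM"):
# reference = sample whose 75th CPM percentile is closest to the mean,
# M/A doubly trimmed (30% / 5%), precision-weighted mean of retained M.
#' TMM normalization to a log2 expression matrix
#'
#' Computes trimmed-mean-of-M-values normalization factors (rescaled to
#' geometric mean 1) and returns log2 CPM on effective library sizes
#' (`libsize x factor`) with a +0.5 offset.
#'
#' @param x a filtered [coex_counts()] with >= 2 samples.
#' @param trim_M log-ratio trim fraction (each tail).
#' @param trim_A mean-abundance trim fraction (each tail).
#' @return a `coex_expr` with `values`, `tmm_factors`, `lib_size`.
#' @export
tmm_normalize <- function(x, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(inherits(x, "coex_counts"))
  if (ncol(x$counts) < 2) stop_coex("TMM needs >= 2 samples")
  lib <- colSums(x$counts)
  f <- edgeR::calcNormFactors(x$counts, method = "TMM", lib.size = lib,
                              logratioTrim = trim_M, sumTrim = trim_A)
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop_coex("TMM factors undefined; a sample shares no expressed genes with the reference")
  }
  eff <- lib * f
  values <- log2(sweep(x$counts, 2, eff, "/") * 1e6 + 0.5)
  new_coex_expr(values, setNames(f, colnames(x$counts)), lib,
                x$sample_meta, x$filter_log)
}

#' Bin RPKM values into expression categories
#'
#' Left-open, right-closed bins: zero = `"not_expressed"`, `(0, 5]` low,
#' `(5, 50]` moderate, `(50, Inf)` high by default. Custom (e.g. six-bin)
#' edges may be supplied as the inner breakpoints.
#'
#' @param rpkm non-negative RPKM matrix.
#' @param edges increasing inner bin edges (default `c(5, 50)`).
#' @param labels category labels, `length(edges) + 1` of them.
#' @return a character matrix of categories, same shape as `rpkm`.
#' @export
bin_expression <- function(rpkm, edges = c(5, 50),
                           labels = c("low", "moderate", "high")) {
  rpkm <- as.matrix(rpkm)
  if (any(rpkm < 0)) stop_coex("RPKM values must be non-negative")
  if (is.unsorted(edges, strictly = TRUE)) {
    stop_coex("bin edges must be strictly increasing")
  }
  if (length(labels) != length(edges) + 1) {
    stop_coex("need one more label than inner edges")
  }
  br <- c(0, edges, Inf)
  out <- matrix(as.character(cut(rpkm, breaks = br, labels = labels,
                                 right = TRUE)),
                nrow = nrow(rpkm), dimnames = dimnames(rpkm))
  out[rpkm == 0] <- "not_expressed"
  out
}

#' Core genes: expressed in every embryonic stage
#'
#' A gene is "core" when it has at least `min_detect` counts in at least one
#' library of every distinct day of the time course.
#'
#' @param x a [coex_counts()] whose metadata has a `day` column.
#' @param min_detect detection threshold in raw counts (default 1).
#' @return character vector of core gene ids.
#' @export
core_genes <- function(x, min_detect = 1) {
  stopifnot(inherits(x, "coex_counts"))
  days <- x$sample_meta$day
  detected_all <- rep(TRUE, nrow(x$counts))
  for (d in unique(days)) {
    cols <- which(days == d)
    detected_all <- detected_all &
      (apply(x$counts[, cols, drop = FALSE], 1L, max) >= min_detect)
  }
  rownames(x$counts)[detected_all]
}

#' Assembly completeness summary
#'
#' Fraction of assessed reference genes recovered at least partially:
#' `(complete + partial + fragmented) / total * 100`, rounded to two
#' decimals. Covers both CEG-style (complete/partial) and BUSCO-style
#' (complete single + duplicated as `complete`, plus fragmented/missing)
#' tallies.
#'
#' @param complete,partial,fragmented,missing non-negative counts.
#' @return a tibble with the component counts, `total`, and
#'   `recovered_pct`.
#' @export
completeness_summary <- function(complete, partial = 0, fragmented = 0,
                                 missing = 0) {
  vals <- c(complete, partial, fragmented, missing)
  if (any(vals < 0)) stop_coex("counts must be non-negative")
  total <- sum(vals)
  if (total == 0) stop_coex("at least one category must be non-zero")
  tibble(
    complete = complete, partial = partial, fragmented = fragmented,
    missing = missing, total = total,
    recovered_pct = round((complete + partial + fragmented) / total * 100, 2)
  )
}
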