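#' Count matrix with gene lengths and sample metadata
#'
#' The raw input container for the pipeline: a genes x samples matrix of
#' non-negative integer counts, a gene length (bp) per gene, and one metadata
#' row per sample (at least `sample_id` and integer `day`; typically also
#' `individual` and `clade`).
#'
#' @param counts genes x samples non-negative integer matrix with rownames
#'   (gene ids) and colnames (sample ids).
#' @param gene_length positive integer vector of gene lengths in bp, named by
#'   gene or in row order.
#' @param sample_meta data frame with one row per sample; must contain
#'   `sample_id` matching `colnames(counts)` and an integer `day` column.
#' @return an object of class `coex_counts`.
#' @export
coex_counts <- function(counts, gene_length, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  if (any(counts < 0)) stop_coex("counts must be non-negative")
  if (any(counts != round(counts))) stop_coex("counts must be integers")
  gene_length <- as.numeric(gene_length)
  if (length(gene_length) != nrow(counts)) {
    stop_coex("gene_length must have one entry per gene")
  }
  if (any(!is.finite(gene_length)) || any(gene_length <= 0)) {
    stop_coex("gene lengths must be positive")
  }
  names(gene_length) <- rownames(counts)
  sample_meta <- as_tibble(sample_meta)
  if (!"sample_id" %in% names(sample_meta)) {
    stop_coex("sample_meta must contain a sample_id column")
  }
  if (nrow(sample_meta) != ncol(counts)) {
    stop_coex("sample_meta must have one row per sample")
  }
  if (!identical(as.character(sample_meta$sample_id), colnames(counts))) {
    stop_coex("sample_meta$sample_id must match colnames(counts) in order")
  }
  structure(
    list(counts = counts, gene_length = gene_length,
         sample_meta = sample_meta, filter_log = list()),
    class = "coex_counts"
  )
}

#' @export
print.coex_counts <- function(x, ...) {
  cat("<coex_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  if (length(x$filter_log)) {
    for (rec in x$filter_log) {
      cat("  filter ", rec$step, ": ", rec$n_removed, " genes removed (",
          rec$n_after, " kept)\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
dim.coex_counts <- function(x) dim(x$counts)

append_filter_log <- function(x, step, keep, params = list()) {
  rec <- list(step = step, n_before = length(keep),
              n_removed = sum(!keep), n_after = sum(keep), params = params)
  x$filter_log <- c(x$filter_log, list(rec))
  x
}

subset_counts <- function(x, keep) {
  x$counts <- x$counts[keep, , drop = FALSE]
  x$gene_length <- x$gene_length[keep]
  x
}

#' Normalized log2 expression matrix
#'
#' Container for the filtered, TMM-normalized, log2-scale expression values,
#' as produced by [tmm_normalize()]. Carries the per-sample normalization
#' factors (geometric mean 1), the effective library sizes, and the filter
#' log inherited from the count matrix.
#'
#' @name coex_expr
#' @seealso [tmm_normalize()]
NULL

new_coex_expr <- function(values, tmm_factors, lib_size, sample_meta,
                          filter_log = list()) {
  structure(
    list(values = values, tmm_factors = tmm_factors, lib_size = lib_size,
         sample_meta = sample_meta, filter_log = filter_log),
    class = "coex_expr"
  )
}

#' @export
print.coex_expr <- function(x, ...) {
  cat("<coex_expr> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (log2 TMM-normalized CPM)\n", sep = "")
  cat("  TMM factors: ", paste(sprintf("%.3f", x$tmm_factors), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.coex_expr <- function(x) dim(x$values)
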