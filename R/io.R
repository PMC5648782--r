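#' Read and write pipeline artifacts
#'
#' All matrices travel as TSV (genes in rows, first column = gene id, header
#' = sample ids), gene lengths as two-column TSV, traits as TSV, planted
#' truth and filter logs as JSON, dendrograms as Newick.
#'
#' @param x object to write (see individual functions).
#' @param path file path.
#' @name coex_io
NULL

#' @rdname coex_io
#' @export
write_matrix_tsv <- function(x, path) {
  m <- if (inherits(x, "coex_expr")) x$values else as.matrix(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname coex_io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname coex_io
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "coex_counts"))
  base <- sub("\\.tsv$", "", path)
  write_matrix_tsv(x$counts, path)
  write.table(data.frame(gene = names(x$gene_length),
                         length_bp = as.integer(x$gene_length)),
              paste0(base, "_lengths.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$sample_meta, paste0(base, "_samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname coex_io
#' @export
read_counts_tsv <- function(path) {
  base <- sub("\\.tsv$", "", path)
  counts <- read_matrix_tsv(path)
  lengths <- read.table(paste0(base, "_lengths.tsv"), sep = "\t",
                        header = TRUE)
  meta <- read.table(paste0(base, "_samples.tsv"), sep = "\t", header = TRUE)
  coex_counts(counts, setNames(lengths$length_bp, lengths$gene), meta)
}

#' @rdname coex_io
#' @export
write_truth_json <- function(x, path) {
  stopifnot(inherits(x, "coex_truth"))
  jsonlite::write_json(
    list(module = as.list(x$module),
         covariate = as.list(x$covariate),
         trajectories = x$trajectories),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname coex_io
#' @param gaf treat the file as GAF-style (tab-separated with the gene id in
#'   column 2 and the term id in column 5, comment lines starting with `!`).
#' @export
read_annotation_tsv <- function(path, gaf = FALSE) {
  if (gaf) {
    df <- read.table(path, sep = "\t", header = FALSE, comment.char = "!",
                     quote = "", fill = TRUE, stringsAsFactors = FALSE)
    tibble(gene = df[[2]], term = df[[5]])
  } else {
    df <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    names(df)[1:2] <- c("gene", "term")
    as_tibble(df[, 1:2])
  }
}

#' Export a dendrogram (optionally with bootstrap support) as Newick
#'
#' @param hc an `hclust`, or a `coex_boot` object (whose AU values are then
#'   written as node labels, in percent).
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  if (inherits(hc, "coex_boot")) {
    phy <- ape::as.phylo(hc$hclust)
    # ape node order: root first, then in as.phylo's internal renumbering
    phy$node.label <- sprintf("%.0f", 100 * au_by_phylo_node(hc, phy))
    ape::write.tree(phy, file = path)
  } else {
    ape::write.tree(ape::as.phylo(hc), file = path)
  }
  invisible(path)
}

au_by_phylo_node <- function(boot, phy) {
  # match hclust merge nodes to phylo internal nodes via leaf sets
  n <- length(phy$tip.label)
  hc_sets <- cluster_keys(boot$hclust)
  labs <- boot$hclust$labels %||% as.character(seq_len(n))
  hc_keys <- vapply(hc_sets$leaves, function(l)
    paste(sort(labs[l]), collapse = ","), character(1))
  au <- setNames(boot$table$au, hc_keys)
  vapply(seq_len(phy$Nnode), function(i) {
    tips <- ape::extract.clade(phy, n + i)$tip.label
    key <- paste(sort(tips), collapse = ",")
    if (key %in% names(au)) au[[key]] else NA_real_
  }, numeric(1))
}
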