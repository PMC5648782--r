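#' Correlation distance between samples
#'
#' `d_ij = 1 - Pearson correlation` between sample expression profiles,
#' computed over all genes.
#'
#' @param expr a `coex_expr` or genes x samples matrix (>= 3 samples).
#' @return a symmetric samples x samples dissimilarity matrix in `[0, 2]`.
#' @export
sample_cor_dist <- function(expr) {
  x <- if (inherits(expr, "coex_expr")) expr$values else as.matrix(expr)
  if (ncol(x) < 3) stop_coex("need >= 3 samples")
  const <- apply(x, 2L, sd) == 0
  if (any(const)) {
    stop_coex(paste0("constant sample(s): ",
                     paste(colnames(x)[const], collapse = ", ")))
  }
  1 - cor(x)
}

#' Complete-linkage clustering of samples
#'
#' @param diss square symmetric dissimilarity (e.g. from
#'   [sample_cor_dist()]).
#' @return an `hclust` object.
#' @export
hclust_complete <- function(diss) {
  d <- as.matrix(diss)
  if (any(is.na(d))) stop_coex("dissimilarity contains NA/NaN")
  hclust(as.dist(d), method = "complete")
}

cluster_keys <- function(hc) {
  n <- length(hc$order)
  leaves <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    ch <- hc$merge[i, ]
    lv <- lapply(ch, function(c) if (c < 0) -c else leaves[[c]])
    leaves[[i]] <- sort(c(lv[[1]], lv[[2]]))
  }
  list(keys = vapply(leaves, paste, character(1), collapse = ","),
       leaves = leaves)
}

#' Multiscale bootstrap support for sample clustering
#'
#' Assesses each cluster of the complete-linkage, correlation-distance
#' sample dendrogram by resampling *genes* with replacement at several
#' relative sizes (scales). For each scale `r`, `B` resamples of
#' `round(r x n_genes)` genes are drawn, samples are reclustered, and the
#' fraction of resamples containing the cluster (exact leaf-set match) gives
#' `BP_r`. The multiscale transform `z_r = qnorm(1 - BP_r)` is fitted by
#' weighted least squares to `z_r = v sqrt(r) + c / sqrt(r)` (weights from
#' the binomial variance of `BP_r`), giving the approximately unbiased
#' support `AU = 1 - pnorm(v - c)`. `BP` is reported at scale 1. Only scales
#' whose counts fall strictly inside `(0, B)` constrain the fit; a cluster
#' recovered in every resample (or none) at nearly all scales carries no
#' curvature information, and its raw BP is reported as AU (so a cluster
#' present in every resample at every scale gets `BP = AU = 1`, and one
#' never observed gets `AU = 0` with a flag).
#'
#' @param expr a `coex_expr` or genes x samples matrix (>= 3 samples, >= 10
#'   genes).
#' @param scales relative resample sizes (default `seq(0.5, 1.4, 0.1)`).
#' @param B bootstrap replicates per scale (default 10000).
#' @param seed integer seed; identical seeds reproduce BP/AU exactly.
#' @return a `coex_boot` object: `hclust` (the observed dendrogram) and
#'   `table`, one row per internal cluster with leaf set, `bp`, `au`, the
#'   fit coefficients `v` and `c`, the weighted residual sum of squares, and
#'   a `never_observed` flag (such clusters get AU = 0).
#' @export
multiscale_bootstrap <- function(expr, scales = seq(0.5, 1.4, by = 0.1),
                                 B = 10000, seed = 1) {
  x <- if (inherits(expr, "coex_expr")) expr$values else as.matrix(expr)
  n <- ncol(x)
  G <- nrow(x)
  if (n < 3) stop_coex("need >= 3 samples")
  if (G < 10) stop_coex("need >= 10 genes")
  if (B < 100) warn("B < 100 gives unstable support values")
  hc <- hclust_complete(sample_cor_dist(x))
  ck <- cluster_keys(hc)
  n_cl <- length(ck$keys)

  set.seed(seed)
  counts <- matrix(0L, nrow = n_cl, ncol = length(scales))
  for (s in seq_along(scales)) {
    m <- max(2L, round(scales[s] * G))
    for (b in seq_len(B)) {
      idx <- sample.int(G, m, replace = TRUE)
      xs <- x[idx, , drop = FALSE]
      sds <- apply(xs, 2L, sd)
      if (any(sds == 0)) next  # degenerate resample: supports nothing
      hb <- hclust(as.dist(1 - cor(xs)), method = "complete")
      kb <- cluster_keys(hb)$keys
      hit <- ck$keys %in% kb
      counts[hit, s] <- counts[hit, s] + 1L
    }
  }
  bp_mat <- counts / B
  r_near1 <- which.min(abs(scales - 1))

  fit_one <- function(i) {
    if (all(counts[i, ] == 0L)) {
      return(list(au = 0, v = NA_real_, c = NA_real_, rss = NA_real_,
                  never = TRUE))
    }
    # only scales with counts strictly inside (0, B) constrain the fit; a
    # cluster seen in every (or no) resample at nearly all scales carries no
    # curvature information and gets its raw BP as the support value
    use <- counts[i, ] > 0L & counts[i, ] < B
    if (sum(use) < 2) {
      return(list(au = bp_mat[i, r_near1], v = NA_real_, c = NA_real_,
                  rss = NA_real_, never = FALSE))
    }
    bp <- pmin(pmax(bp_mat[i, use], 1 / (B + 1)), B / (B + 1))
    z <- qnorm(1 - bp)
    wt <- B * stats::dnorm(z)^2 / (bp * (1 - bp))
    X <- cbind(sqrt(scales[use]), 1 / sqrt(scales[use]))
    fit <- lm.wfit(X, z, wt)
    v <- fit$coefficients[1]
    c0 <- fit$coefficients[2]
    list(au = 1 - pnorm(v - c0), v = v, c = c0,
         rss = sum(wt * fit$residuals^2), never = FALSE)
  }
  fits <- map(seq_len(n_cl), fit_one)
  tab <- tibble(
    cluster = seq_len(n_cl),
    members = map_chr(ck$leaves, function(l)
      paste(hc$labels[l] %||% l, collapse = ",")),
    size = map_int(ck$leaves, length),
    bp = bp_mat[, r_near1],
    au = map_dbl(fits, "au"),
    v = map_dbl(fits, "v"),
    c = map_dbl(fits, "c"),
    wls_rss = map_dbl(fits, "rss"),
    never_observed = map_dbl(fits, function(f) as.numeric(f$never)) > 0
  )
  structure(list(hclust = hc, table = tab, bp_by_scale = bp_mat,
                 scales = scales, B = B, seed = seed),
            class = "coex_boot")
}

#' @export
print.coex_boot <- function(x, ...) {
  cat("<coex_boot> ", length(x$hclust$order), " samples, ",
      nrow(x$table), " clusters, B = ", x$B, " x ",
      length(x$scales), " scales\n", sep = "")
  invisible(x)
}

#' Classical multidimensional scaling
#'
#' Torgerson scaling: double-center `-d^2 / 2`, take the top `k`
#' eigenvectors scaled by the root eigenvalues. Dimensions with
#' non-positive eigenvalues are dropped (the eigenvalues are reported so
#' non-Euclidean input is visible).
#'
#' @param diss samples x samples dissimilarity matrix.
#' @param k target dimension (default 2; must be `<= n - 1`).
#' @return a `coex_mds` object: `points` (samples x <= k), `eig` (all
#'   eigenvalues), `k_used`.
#' @export
classical_mds <- function(diss, k = 2) {
  d <- as.matrix(diss)
  n <- nrow(d)
  if (k > n - 1) stop_coex("k must be <= n - 1")
  fit <- cmdscale(as.dist(d), k = k, eig = TRUE)
  pos <- fit$eig[seq_len(k)] > sqrt(.Machine$double.eps)
  pts <- fit$points[, pos, drop = FALSE]
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  structure(list(points = pts, eig = fit$eig, k_requested = k,
                 k_used = ncol(pts)),
            class = "coex_mds")
}

#' @export
print.coex_mds <- function(x, ...) {
  cat("<coex_mds> ", nrow(x$points), " samples in ", x$k_used,
      " dimensions (", sum(x$eig < -1e-8), " negative eigenvalues)\n",
      sep = "")
  invisible(x)
}
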