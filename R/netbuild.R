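#' Biweight midcorrelation matrix
#'
#' Robust gene-gene correlation. Per gene: with `m` the median and `d` the
#' (unscaled) median absolute deviation, `u_i = (x_i - m) / (9 d)`; Tukey
#' biweight weights `w_i = (1 - u_i^2)^2 1(|u_i| < 1)`; the correlation is the
#' normalized weighted cross-product of `(x_i - m) w_i`. Before weighting,
#' each side of `u` is rescaled independently so that at most `maxPOutliers`
#' of the samples on that side receive zero weight: when the side's
#' `maxPOutliers` quantile of `u` lies beyond +-1 the side is shrunk so that
#' quantile maps exactly to +-1.
#'
#' Genes with `d = 0` (median-constant profiles) fall back to Pearson
#' centering with unit weights and are flagged in the `"pearson_fallback"`
#' attribute.
#'
#' @param expr a `coex_expr` or a genes x samples numeric matrix (>= 4
#'   samples, finite values).
#' @param maxPOutliers maximum fraction of samples treated as outliers on
#'   each side, in `(0, 0.5]`.
#' @return symmetric genes x genes correlation matrix, unit diagonal, with
#'   attributes `method = "bicor"`, `maxPOutliers`, `pearson_fallback`.
#' @export
bicor_matrix <- function(expr, maxPOutliers = 0.1) {
  x <- if (inherits(expr, "coex_expr")) expr$values else as.matrix(expr)
  n <- ncol(x)
  if (n < 4) stop_coex("bicor needs >= 4 samples")
  if (any(!is.finite(x))) stop_coex("expression values must be finite")
  if (maxPOutliers <= 0 || maxPOutliers > 0.5) {
    stop_coex("maxPOutliers must be in (0, 0.5]")
  }
  med <- apply(x, 1L, median)
  madv <- apply(abs(x - med), 1L, median)
  fallback <- madv == 0

  centred <- x - med
  u <- centred / (9 * madv)
  u[fallback, ] <- 0  # keep quantiles finite; these rows are replaced below
  # side-specific capping: the maxPOutliers quantile must not exceed |1|
  qlo <- apply(u, 1L, quantile, probs = maxPOutliers, names = FALSE)
  qhi <- apply(u, 1L, quantile, probs = 1 - maxPOutliers, names = FALSE)
  scale_neg <- ifelse(qlo < -1, -qlo, 1)
  scale_pos <- ifelse(qhi > 1, qhi, 1)
  neg <- u < 0
  u[neg] <- u[neg] / scale_neg[row(u)[neg]]
  u[!neg] <- u[!neg] / scale_pos[row(u)[!neg]]
  w <- (1 - u^2)^2 * (abs(u) < 1)

  g <- centred * w
  if (any(fallback)) {
    xf <- x[fallback, , drop = FALSE]
    g[fallback, ] <- xf - rowMeans(xf)
  }
  norms <- sqrt(rowSums(g^2))
  if (any(norms == 0)) {
    # fully constant profile: correlation undefined, returned as 0 off-diagonal
    norms[norms == 0] <- Inf
  }
  g <- g / norms
  r <- tcrossprod(g)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(rownames(x), rownames(x))
  structure(r, method = "bicor", maxPOutliers = maxPOutliers,
            pearson_fallback = which(fallback), n_samples = n)
}

#' Signed-hybrid adjacency
#'
#' `a_ij = cor_ij ^ beta` where the correlation is positive, 0 otherwise
#' (off-diagonal); the diagonal is 1. Negative co-expression carries no edge.
#'
#' @param cor_mat symmetric correlation matrix in `[-1, 1]`.
#' @param beta soft-threshold power (>= 1).
#' @param max_genes guard on dense-matrix size (default 5000 genes).
#' @return adjacency matrix in `[0, 1]`.
#' @export
adjacency_signed_hybrid <- function(cor_mat, beta, max_genes = 5000) {
  if (beta < 1) stop_coex("beta must be >= 1")
  if (nrow(cor_mat) > max_genes) {
    stop_coex(paste0("dense network capped at ", max_genes,
                     " genes; raise max_genes explicitly for larger inputs"))
  }
  a <- ifelse(cor_mat > 0, cor_mat^beta, 0)
  diag(a) <- 1
  a
}

#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate power: form the signed-hybrid adjacency, compute
#' connectivities `k_i = sum_{j != i} a_ij`, bin genes into `n_bins`
#' equal-width bins of `k`, and regress `log10(frequency)` on
#' `log10(mean k)` over non-empty bins. The signed fit index is
#' `-sign(slope) * R^2`. The chosen power is the smallest candidate whose
#' signed `R^2` reaches `target_R2`, or the argmax when none does.
#' Degenerate powers (all connectivities equal, or fewer than 3 usable bins)
#' are flagged and never chosen.
#'
#' At large powers the adjacency of a dense network disintegrates and its
#' connectivity tail mimics a power law, so the fit index can cross the
#' target spuriously: crossings above `max_reasonable_power` (15 by default,
#' the usual bound quoted for unsigned and signed-hybrid networks) are
#' therefore reported but not selected. When no candidate reaches the target
#' within the reasonable range, the default fallback is the standard
#' sample-size guideline for signed-hybrid networks (power 9 below 20
#' samples, 8 for 20-30, 7 for 30-40, 6 above); set `fallback = "argmax"`
#' to take the best-fitting power instead.
#'
#' @param cor_mat correlation matrix (from [bicor_matrix()] or Pearson).
#' @param powers candidate integer powers (default 1:30).
#' @param target_R2 signed scale-free fit target (default 0.85).
#' @param n_bins connectivity histogram bins (default 10).
#' @param fallback `"guideline"` (default) or `"argmax"`: rule used when no
#'   candidate reaches `target_R2` within the reasonable range.
#' @param max_reasonable_power largest power at which a target crossing is
#'   trusted (default 15).
#' @param n_samples sample count behind the correlations, needed by the
#'   guideline fallback; taken from the `bicor_matrix()` attribute when
#'   present.
#' @return a `coex_sft` object: tibble `fit` (power, r_squared, slope,
#'   mean_k, median_k, max_k, degenerate), `power` (the chosen one), and
#'   `reached_target`.
#' @export
pick_soft_threshold <- function(cor_mat, powers = 1:30, target_R2 = 0.85,
                                n_bins = 10,
                                fallback = c("guideline", "argmax"),
                                max_reasonable_power = 15,
                                n_samples = attr(cor_mat, "n_samples")) {
  fallback <- match.arg(fallback)
  if (nrow(cor_mat) < n_bins) stop_coex("need at least n_bins genes")
  pos <- ifelse(cor_mat > 0, cor_mat, 0)
  diag(pos) <- 0
  rows <- map(powers, function(b) {
    k <- rowSums(pos^b)
    if (all(k == 0)) stop_coex("all connectivities are zero")
    res <- scale_free_fit(k, n_bins)
    tibble(power = b, r_squared = res$r2, slope = res$slope,
           mean_k = mean(k), median_k = median(k), max_k = max(k),
           degenerate = res$degenerate)
  })
  fit <- bind_rows(rows)
  eligible <- fit[!fit$degenerate, , drop = FALSE]
  if (nrow(eligible) == 0) {
    stop_coex("scale-free fit degenerate at every candidate power")
  }
  ok <- eligible$power[eligible$r_squared >= target_R2 &
                         eligible$power <= max_reasonable_power]
  reached <- length(ok) > 0
  power <- if (reached) {
    min(ok)
  } else if (fallback == "argmax") {
    eligible$power[which.max(eligible$r_squared)]
  } else {
    if (is.null(n_samples)) {
      stop_coex("guideline fallback needs n_samples (or use fallback = \"argmax\")")
    }
    guide <- if (n_samples < 20) 9 else if (n_samples < 30) 8
      else if (n_samples < 40) 7 else 6
    eligible$power[which.min(abs(eligible$power - guide))]
  }
  structure(list(fit = fit, power = power, target_R2 = target_R2,
                 n_bins = n_bins, reached_target = reached,
                 fallback = fallback),
            class = "coex_sft")
}

scale_free_fit <- function(k, n_bins) {
  if (sd(k) == 0) {
    return(list(r2 = NA_real_, slope = NA_real_, degenerate = TRUE))
  }
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  mean_k <- tapply(k, cuts, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(keep) < 3) {
    return(list(r2 = NA_real_, slope = NA_real_, degenerate = TRUE))
  }
  lx <- log10(mean_k[keep])
  ly <- log10(freq[keep])
  fit <- lm(ly ~ lx)
  sl <- coef(fit)[2]
  r2 <- summary(fit)$r.squared
  list(r2 = as.numeric(-sign(sl) * r2), slope = as.numeric(sl),
       degenerate = FALSE)
}

#' @export
print.coex_sft <- function(x, ...) {
  cat("<coex_sft> chosen power ", x$power, " (signed R^2 = ",
      sprintf("%.3f", x$fit$r_squared[x$fit$power == x$power]),
      ", target ", x$target_R2, ")\n", sep = "")
  invisible(x)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with connectivity `k` excluding the diagonal; `TOM_ii = 1`. The
#' dissimilarity used for clustering is `1 - TOM`.
#'
#' @param adjacency symmetric adjacency in `[0, 1]` (unit diagonal).
#' @return a `coex_network` object with `adjacency`, `tom`, `diss_tom`.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < 0 | a > 1)) stop_coex("adjacency must lie in [0, 1]")
  if (max(abs(a - t(a))) > 1e-10) stop_coex("adjacency must be symmetric")
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(a0)
  num <- a0 %*% a0 + a0
  den <- outer(k, k, pmin) + 1 - a0
  den[den <= 0] <- 1  # unreachable for adjacency in [0,1); guarded anyway
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  structure(list(adjacency = a, tom = tom, diss_tom = 1 - tom,
                 type = "signed-hybrid"),
            class = "coex_network")
}

#' Build the full signed-hybrid network in one call
#'
#' Convenience wrapper: bicor -> (optional) soft-threshold selection ->
#' adjacency -> TOM.
#'
#' @param expr a `coex_expr` or matrix.
#' @param beta fixed power; when `NULL` it is chosen by
#'   [pick_soft_threshold()].
#' @param maxPOutliers passed to [bicor_matrix()].
#' @param powers,target_R2 passed to [pick_soft_threshold()].
#' @param max_genes dense-size guard.
#' @return a `coex_network` with the extra fields `beta`, `sft` (when
#'   auto-selected) and `correlation`.
#' @export
build_network <- function(expr, beta = NULL, maxPOutliers = 0.1,
                          powers = 1:30, target_R2 = 0.85, max_genes = 5000) {
  r <- bicor_matrix(expr, maxPOutliers = maxPOutliers)
  sft <- NULL
  if (is.null(beta)) {
    sft <- pick_soft_threshold(r, powers = powers, target_R2 = target_R2)
    beta <- sft$power
  }
  a <- adjacency_signed_hybrid(r, beta, max_genes = max_genes)
  net <- tom_similarity(a)
  net$beta <- beta
  net$sft <- sft
  net$correlation <- r
  net
}

#' @export
print.coex_network <- function(x, ...) {
  cat("<coex_network> ", nrow(x$tom), " genes, signed-hybrid",
      if (!is.null(x$beta)) paste0(", beta = ", x$beta), "\n", sep = "")
  invisible(x)
}
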