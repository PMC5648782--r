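#' Average-linkage clustering of a dissimilarity matrix
#'
#' @param diss square symmetric dissimilarity matrix (e.g. `1 - TOM`).
#' @return an `hclust` object.
#' @export
hclust_average <- function(diss) {
  d <- as.matrix(diss)
  if (any(is.na(d))) stop_coex("dissimilarity contains NA/NaN")
  hclust(as.dist(d), method = "average")
}

# deepSplit -> fraction of the tree's height spread the profile cutoff sits
# below the maximum merge height; larger deep_split cuts deeper (finer)
deep_split_gap <- function(deep_split) {
  if (deep_split < 0 || deep_split > 4) stop_coex("deep_split must be in 0..4")
  0.05 + 0.05 * deep_split
}

#' Dynamic branch cut of a dendrogram
#'
#' Adaptive, fully deterministic branch detection by height-profile analysis
#' along the merge order. Each gap between adjacent leaves in the dendrogram
#' display order corresponds to exactly one internal node (the one whose two
#' child spans meet there); the profile of these boundary heights shows
#' tight branches as contiguous valleys separated by high peaks. Boundaries
#' below the adaptive cutoff `max(h) - g x (max(h) - min(h))` (with `g`
#' growing with `deep_split`) are "low"; every maximal run of leaves joined
#' by low boundaries with at least `min_module_size` members becomes a
#' module, everything else — loose leaves, shallow branches, diffuse noise,
#' where merge heights crowd the top of the tree — stays unassigned
#' (label 0). A module chained upward by stragglers keeps its core; the
#' stragglers stay unassigned.
#'
#' @param dend an `hclust` object (from [hclust_average()]).
#' @param min_module_size smallest run reported as a module (default 50).
#' @param deep_split split sensitivity 0 (coarse) .. 4 (fine), default 2.
#' @return integer labels per leaf, 0 = unassigned, modules numbered by
#'   decreasing size.
#' @export
cut_dynamic <- function(dend, min_module_size = 50, deep_split = 2) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$order)
  if (min_module_size > n) stop_coex("min_module_size exceeds number of leaves")
  merge <- dend$merge
  height <- dend$height
  g <- deep_split_gap(deep_split)

  # boundary height profile: position of each internal node's child-span
  # boundary in the leaf display order
  pos <- integer(n)
  pos[dend$order] <- seq_len(n)
  lo <- hi <- integer(nrow(merge))
  boundary <- numeric(n - 1)
  for (i in seq_len(nrow(merge))) {
    ch <- merge[i, ]
    rng <- vapply(ch, function(c) {
      if (c < 0) c(pos[-c], pos[-c]) else c(lo[c], hi[c])
    }, numeric(2))
    lo[i] <- min(rng)
    hi[i] <- max(rng)
    boundary[min(rng[2, ])] <- height[i]  # right edge of the left span
  }

  cutoff <- max(height) - g * (max(height) - min(height))
  low <- boundary < cutoff
  labels <- integer(n)
  next_id <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && low[j]) j <- j + 1L
    if (j - i + 1L >= min_module_size) {
      next_id <- next_id + 1L
      labels[dend$order[i:j]] <- next_id
    }
    i <- j + 1L
  }
  relabel_by_size(labels, dend$labels)
}

relabel_by_size <- function(labels, names = NULL) {
  ids <- setdiff(unique(labels), 0L)
  if (length(ids)) {
    sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
    remap <- setNames(order(order(-sizes)), ids)  # rank by decreasing size
    labels <- ifelse(labels == 0L, 0L, remap[as.character(labels)])
  }
  labels <- as.integer(labels)
  if (!is.null(names)) names(labels) <- names
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized expression: member gene profiles are scaled to zero mean and
#' unit variance, and the first right singular vector across samples is
#' taken, oriented so that its mean correlation with the member genes is
#' non-negative. Constant genes are excluded with a warning. The unassigned
#' label 0 gets no eigengene.
#'
#' @param expr a `coex_expr` or genes x samples matrix.
#' @param labels integer module labels per gene (0 = unassigned).
#' @return a `coex_me` object: `eigengenes` (modules x samples, unit-norm
#'   rows, rownames `ME<k>`) and `var_explained` per module.
#' @export
module_eigengenes <- function(expr, labels) {
  x <- if (inherits(expr, "coex_expr")) expr$values else as.matrix(expr)
  stopifnot(length(labels) == nrow(x))
  ids <- sort(setdiff(unique(labels), 0L))
  if (!length(ids)) stop_coex("no modules to summarize")
  me <- matrix(NA_real_, nrow = length(ids), ncol = ncol(x),
               dimnames = list(paste0("ME", ids), colnames(x)))
  ve <- setNames(numeric(length(ids)), paste0("ME", ids))
  for (j in seq_along(ids)) {
    rows <- which(labels == ids[j])
    xm <- x[rows, , drop = FALSE]
    keep <- apply(xm, 1L, sd) > 0
    if (!all(keep)) {
      warn(paste0("module ", ids[j], ": excluding ", sum(!keep),
                  " constant gene(s) from its eigengene"))
      xm <- xm[keep, , drop = FALSE]
    }
    if (nrow(xm) < 2) stop_coex("modules need >= 2 non-constant genes")
    xs <- scale_rows(xm)
    sv <- svd(xs)
    v <- sv$v[, 1]
    if (mean(cor(v, t(xs))) < 0) v <- -v
    me[j, ] <- v
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = me, var_explained = ve), class = "coex_me")
}

#' Merge modules with correlated eigengenes
#'
#' Iteratively clusters module eigengenes by the dissimilarity
#' `1 - cor(ME)`, average linkage, merges every group joined below
#' `me_diss_threshold` (i.e. eigengene correlation above
#' `1 - me_diss_threshold`), recomputes eigengenes, and repeats until no
#' pair remains below the threshold. The fixed point is idempotent.
#'
#' @param expr a `coex_expr` or matrix.
#' @param labels integer labels from [cut_dynamic()].
#' @param me_diss_threshold eigengene dissimilarity below which modules are
#'   merged (default 0.1, i.e. correlation 0.9).
#' @return a `coex_modules` object: final `labels`, `eigengenes`,
#'   `var_explained`, `pre_merge_labels`, `n_pre_merge`, `merge_history`.
#' @export
merge_modules <- function(expr, labels, me_diss_threshold = 0.1) {
  x <- if (inherits(expr, "coex_expr")) expr$values else as.matrix(expr)
  pre <- labels
  history <- list()
  repeat {
    ids <- sort(setdiff(unique(labels), 0L))
    if (length(ids) < 2) break
    me <- module_eigengenes(x, labels)
    d <- 1 - cor(t(me$eigengenes))
    hc <- hclust(as.dist(d), method = "average")
    grp <- cutree(hc, h = me_diss_threshold)
    if (max(grp) == length(ids)) break
    map <- setNames(grp, ids)
    history[[length(history) + 1L]] <-
      tibble(from = ids, to = as.integer(map[as.character(ids)]))
    labels <- ifelse(labels == 0L, 0L, map[as.character(labels)])
  }
  labels <- relabel_by_size(as.integer(labels), names(pre))
  me <- module_eigengenes(x, labels)
  structure(
    list(labels = labels, eigengenes = me$eigengenes,
         var_explained = me$var_explained,
         pre_merge_labels = pre,
         n_pre_merge = length(setdiff(unique(pre), 0L)),
         n_modules = length(setdiff(unique(labels), 0L)),
         me_diss_threshold = me_diss_threshold,
         merge_history = history),
    class = "coex_modules"
  )
}

#' @export
print.coex_modules <- function(x, ...) {
  cat("<coex_modules> ", x$n_modules, " modules (", x$n_pre_merge,
      " before merging), ", sum(x$labels == 0), " unassigned genes\n",
      sep = "")
  invisible(x)
}

#' Color aliases for module ids
#'
#' Maps the stable integer module ids to conventional module color names
#' for report parity with the usual co-expression naming scheme; 0 stays
#' `"grey"` (unassigned). Ids beyond the palette get `"module<k>"`.
#'
#' @param labels integer module labels (0 = unassigned).
#' @return character vector of color names, same length and names.
#' @export
module_color_alias <- function(labels) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue", "darkred",
               "darkgreen", "darkturquoise", "darkgrey", "orange",
               "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
               "paleturquoise", "violet", "darkolivegreen", "darkmagenta")
  out <- ifelse(labels == 0L, "grey",
                ifelse(labels <= length(palette), palette[pmax(labels, 1L)],
                       paste0("module", labels)))
  names(out) <- names(labels)
  out
}

#' Module-trait correlation
#'
#' Pearson correlation of every module eigengene with every numeric trait,
#' with two-sided Student-t p-values (`n - 2` df) and Benjamini-Hochberg
#' adjustment, by default within each trait family.
#'
#' @param modules a `coex_modules` or `coex_me` object (or an eigengene
#'   matrix, modules x samples).
#' @param traits data frame with `sample_id` plus numeric trait columns, in
#'   sample order matching the eigengene columns.
#' @param adjust_family `"per_trait"` (default) or `"global"` BH family.
#' @return a `coex_module_trait` object whose `table` is a tibble with
#'   module, trait, r, p, fdr, n.
#' @export
module_trait_cor <- function(modules, traits,
                             adjust_family = c("per_trait", "global")) {
  adjust_family <- match.arg(adjust_family)
  me <- extract_me(modules)
  tr <- as_tibble(traits)
  tr_num <- tr[setdiff(names(tr), "sample_id")]
  stopifnot(all(vapply(tr_num, is.numeric, logical(1))))
  n <- ncol(me)
  if (nrow(tr_num) != n) stop_coex("traits must align with eigengene samples")
  if (n < 4) stop_coex("need >= 4 samples")
  constant <- vapply(tr_num, function(v) sd(v) == 0, logical(1))
  if (any(constant)) {
    warn(paste0("constant trait(s) reported as NA: ",
                paste(names(tr_num)[constant], collapse = ", ")))
  }
  r <- suppressWarnings(cor(t(me), as.matrix(tr_num)))
  p <- matrix(cor_pvalue(r, n), nrow = nrow(r), dimnames = dimnames(r))
  p[, constant] <- NA_real_
  r[, constant] <- NA_real_
  fdr <- if (adjust_family == "per_trait") {
    apply(p, 2L, p.adjust, method = "BH")
  } else {
    matrix(p.adjust(p, method = "BH"), nrow = nrow(p), dimnames = dimnames(p))
  }
  tab <- tibble(
    module = rep(rownames(r), times = ncol(r)),
    trait = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), p = as.vector(p), fdr = as.vector(fdr), n = n
  )
  structure(list(table = tab, r = r, p = p, fdr = fdr, n = n,
                 adjust_family = adjust_family),
            class = "coex_module_trait")
}

extract_me <- function(modules) {
  if (inherits(modules, "coex_modules") || inherits(modules, "coex_me")) {
    modules$eigengenes
  } else {
    as.matrix(modules)
  }
}

#' @export
print.coex_module_trait <- function(x, ...) {
  cat("<coex_module_trait> ", nrow(x$r), " modules x ", ncol(x$r),
      " traits, n = ", x$n, " samples\n", sep = "")
  sig <- sum(x$fdr < 0.05, na.rm = TRUE)
  cat("  ", sig, " associations at FDR < 0.05\n", sep = "")
  invisible(x)
}

#' Module membership (kME)
#'
#' `kME_gm` is the Pearson correlation of gene `g`'s expression profile with
#' module `m`'s eigengene, with the usual Student-t p-value. All genes get a
#' kME in every module column, including unassigned genes.
#'
#' @param expr a `coex_expr` or matrix.
#' @param modules a `coex_modules`/`coex_me` object or eigengene matrix.
#' @return a `coex_kme` object with matrices `kme` and `p`
#'   (genes x modules).
#' @export
kme <- function(expr, modules) {
  x <- if (inherits(expr, "coex_expr")) expr$values else as.matrix(expr)
  me <- extract_me(modules)
  stopifnot(ncol(x) == ncol(me))
  keep <- apply(x, 1L, sd) > 0
  k <- matrix(NA_real_, nrow(x), nrow(me),
              dimnames = list(rownames(x), rownames(me)))
  k[keep, ] <- cor(t(x[keep, , drop = FALSE]), t(me))
  p <- matrix(cor_pvalue(k, ncol(x)), nrow = nrow(k), dimnames = dimnames(k))
  structure(list(kme = k, p = p, n = ncol(x)), class = "coex_kme")
}

#' Intramodular hub genes
#'
#' Hub genes of a module are its members whose kME exceeds `r_min` with a
#' correlation p-value below `p_max`. Note that with few samples the p-value
#' rule binds: at n = 15, kME = 0.9 gives p ~ 4.9e-6 > 1e-6, so a gene at
#' exactly 0.9 is not a hub under the joint rule.
#'
#' @param kme_obj a `coex_kme` from [kme()].
#' @param labels module labels aligned with the kME rows.
#' @param r_min kME threshold (default 0.9, exclusive).
#' @param p_max p-value threshold (default 1e-6, exclusive).
#' @return a tibble with gene, module, kme, p for every hub gene.
#' @export
hub_genes <- function(kme_obj, labels, r_min = 0.9, p_max = 1e-6) {
  stopifnot(inherits(kme_obj, "coex_kme"))
  stopifnot(length(labels) == nrow(kme_obj$kme))
  ids <- sort(setdiff(unique(labels), 0L))
  out <- map(ids, function(m) {
    col <- paste0("ME", m)
    if (!col %in% colnames(kme_obj$kme)) return(NULL)
    rows <- which(labels == m)
    kv <- kme_obj$kme[rows, col]
    pv <- kme_obj$p[rows, col]
    sel <- !is.na(kv) & kv > r_min & pv < p_max
    tibble(gene = rownames(kme_obj$kme)[rows][sel], module = m,
           kme = kv[sel], p = pv[sel])
  })
  bind_rows(out)
}
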