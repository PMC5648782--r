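# Independent brute-force oracles. These deliberately re-derive each quantity
# from its definition (scalar loops, enumeration, literal recipes) and share
# no code with the package internals they check.

# biweight midcorrelation of two vectors, literal formula
oracle_bicor <- function(x, y, maxPOutliers = 1) {
  weight_vec <- function(v) {
    m <- median(v)
    d <- median(abs(v - m))
    u <- (v - m) / (9 * d)
    qlo <- quantile(u, maxPOutliers, names = FALSE)
    qhi <- quantile(u, 1 - maxPOutliers, names = FALSE)
    if (qlo < -1) u[u < 0] <- u[u < 0] / (-qlo)
    if (qhi > 1) u[u > 0] <- u[u > 0] / qhi
    (v - m) * (1 - u^2)^2 * (abs(u) < 1)
  }
  a <- weight_vec(x)
  b <- weight_vec(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# topological overlap, triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# naive agglomerative clustering; returns the cophenetic distance matrix,
# which is invariant to merge-order bookkeeping conventions
oracle_linkage_cophenetic <- function(d, method = c("average", "complete")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  members <- as.list(seq_len(n))
  cd <- d
  coph <- matrix(0, n, n)
  while (length(members) > 1) {
    m <- length(members)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (cd[i, j] < best[1]) best <- c(cd[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    coph[members[[i]], members[[j]]] <- best[1]
    coph[members[[j]], members[[i]]] <- best[1]
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newd <- vapply(seq_len(m), function(k) {
      if (k == i || k == j) return(NA_real_)
      if (method == "average") {
        (ni * cd[i, k] + nj * cd[j, k]) / (ni + nj)
      } else {
        max(cd[i, k], cd[j, k])
      }
    }, numeric(1))
    members[[i]] <- c(members[[i]], members[[j]])
    cd[i, ] <- newd; cd[, i] <- newd; cd[i, i] <- 0
    members <- members[-j]
    cd <- cd[-j, -j, drop = FALSE]
  }
  coph
}

# Benjamini-Hochberg step-up, literal
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# hypergeometric upper tail by explicit enumeration of the 2x2 tables
oracle_hyper_tail <- function(x, term_n, N, draw_n) {
  xs <- x:min(term_n, draw_n)
  sum(choose(term_n, xs) * choose(N - term_n, draw_n - xs)) / choose(N, draw_n)
}

# literal TMM recipe: upper-quartile reference, doubly trimmed M/A,
# precision-weighted mean of retained log-ratios, geometric mean 1
oracle_tmm_factors <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  lib <- colSums(counts)
  q75 <- vapply(seq_len(ncol(counts)), function(j)
    quantile(counts[, j] / lib[j], 0.75, names = FALSE), numeric(1))
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; rfc <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    keep <- obs > 0 & rfc > 0
    obs <- obs[keep]; rfc <- rfc[keep]
    logR <- log2((obs / nO) / (rfc / nR))
    absE <- (log2(obs / nO) + log2(rfc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rfc) / (nR * rfc)
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_M) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_A) + 1; hiS <- n + 1 - loS
    keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# plain bootstrap probability of a sample cluster at scale 1, written as an
# independent loop (own seed handling, no shared code with the package)
oracle_bp_scale1 <- function(x, target_leafset, B, seed) {
  set.seed(seed)
  labels <- colnames(x)
  target <- paste(sort(labels[target_leafset]), collapse = "|")
  hits <- 0L
  for (b in seq_len(B)) {
    xs <- x[sample(nrow(x), nrow(x), replace = TRUE), , drop = FALSE]
    hb <- hclust(as.dist(1 - cor(xs)), method = "complete")
    n <- ncol(x)
    sets <- vector("list", n - 1)
    found <- FALSE
    for (i in seq_len(n - 1)) {
      ch <- hb$merge[i, ]
      lv <- lapply(ch, function(c) if (c < 0) -c else sets[[c]])
      sets[[i]] <- c(lv[[1]], lv[[2]])
      if (paste(sort(labels[sets[[i]]]), collapse = "|") == target) {
        found <- TRUE
      }
    }
    if (found) hits <- hits + 1L
  }
  hits / B
}

# adjacency of three clean expression blocks for planted-structure tests
make_block_diss <- function(sizes, within = 0.1, between = 1) {
  n <- sum(sizes)
  d <- matrix(between, n, n)
  off <- 0
  for (s in sizes) {
    idx <- off + seq_len(s)
    d[idx, idx] <- within
    off <- off + s
  }
  diag(d) <- 0
  d
}
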