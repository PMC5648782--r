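toy_counts <- function(mat, lengths = NULL, days = NULL) {
  if (is.null(lengths)) lengths <- rep(1000L, nrow(mat))
  if (is.null(days)) days <- seq_len(ncol(mat))
  rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  coex_counts(mat, lengths,
              data.frame(sample_id = colnames(mat), day = days))
}

test_that("cpm matches its definition and normalizes columns to 1e6", {
  x <- toy_counts(matrix(c(5, 999995, 10, 999990), ncol = 2))
  expect_equal(cpm_matrix(x)[1, 1], 5)
  m <- matrix(c(3, 7, 2, 8), 2)
  hand <- cbind(c(3, 7) / 10 * 1e6, c(2, 8) / 10 * 1e6)
  expect_equal(unname(cpm_matrix(toy_counts(m))), hand)
  sim <- simulate_counts(sim_config(n_genes = 50, module_sizes = integer(0),
                                    trajectory_kind = character(0), seed = 1))
  expect_equal(colSums(cpm_matrix(sim$counts)), rep(1e6, 15),
               tolerance = 1e-6, ignore_attr = TRUE)
  # all-zero gene stays zero; zero-total sample is named in the error
  x0 <- toy_counts(rbind(c(0, 0), c(5, 5)))
  expect_equal(cpm_matrix(x0)[1, ], c(s1 = 0, s2 = 0))
  expect_error(cpm_matrix(toy_counts(rbind(c(1, 0), c(1, 0)))), "s2")
})

test_that("rpkm matches its definition", {
  x <- toy_counts(matrix(c(10, 9999990), ncol = 1), lengths = c(1000L, 500L))
  expect_equal(rpkm_matrix(x)[1, 1], 1.0)
  expect_equal(rpkm_matrix(toy_counts(rbind(c(0, 0), c(5, 5))))[1, ],
               c(s1 = 0, s2 = 0))
  m <- matrix(c(12, 88, 40, 60), 2)
  len <- c(700L, 2100L)
  hand <- m * 1e9 / rep(colSums(m), each = 2) / len
  expect_equal(unname(rpkm_matrix(toy_counts(m, len))), hand)
  expect_error(rpkm_matrix(matrix(1:4, 2)), "length")
})

test_that("abundance filter applies a library-size aware CPM cutoff", {
  set.seed(1)
  m <- matrix(rpois(40, 20), nrow = 10)
  m[1, ] <- 0                      # never detected
  x <- toy_counts(m)
  f <- filter_abundance(x, min_count = 5)
  # brute-force evaluation of the rule
  cutoff <- 5 / median(colSums(m)) * 1e6
  cpm <- m * 1e6 / rep(colSums(m), each = 10)
  keep <- apply(cpm, 1, max) >= cutoff
  expect_identical(rownames(f$counts), rownames(x$counts)[keep])
  expect_false("g1" %in% rownames(f$counts))
  expect_equal(f$filter_log[[1]]$n_removed, sum(!keep))
  # boundary gene sitting exactly at the cutoff is kept
  depth <- 1e5
  mb <- matrix(c(5, depth - 5, 0, depth), ncol = 2)
  fb <- filter_abundance(toy_counts(mb), min_count = 5)
  expect_true("g1" %in% rownames(fb$counts))
  # strict raw-count mode and validation
  fs <- filter_abundance(x, min_count = 5, strict_counts = TRUE)
  expect_identical(rownames(fs$counts),
                   rownames(x$counts)[apply(m, 1, max) >= 5])
  expect_error(filter_abundance(x, min_count = 0), "min_count")
  # idempotence
  expect_identical(rownames(filter_abundance(f)$counts), rownames(f$counts))
})

test_that("variance filter implements the stated inequality", {
  set.seed(7)
  m <- matrix(rnorm(20 * 6, sd = rep(seq(0.2, 2, length.out = 20), 6)),
              nrow = 20)
  rownames(m) <- paste0("g", 1:20)
  for (st in c("mean", "median", "pooled")) {
    out <- filter_variance(m, factor = 1.5, stat = st)
    v <- apply(m, 1, var)
    overall <- switch(st, mean = mean(v), median = median(v),
                      pooled = var(as.vector(m)))
    expect_identical(rownames(out), rownames(m)[v >= 1.5 * overall])
  }
  # constant gene always removed for positive factor; factor 0 removes none
  m[1, ] <- 3
  expect_false("g1" %in% rownames(filter_variance(m, factor = 0.01)))
  expect_equal(nrow(filter_variance(m, factor = 0)), 20)
  expect_error(filter_variance(m, factor = -1), "non-negative")
  expect_error(filter_variance(m[, 1:2, drop = FALSE]), "samples")
})

test_that("TMM factors are symmetric, depth-invariant and match the literal recipe", {
  set.seed(42)
  base <- rpois(50, 60) + 1
  # identical samples -> unit factors
  x_id <- toy_counts(cbind(base, base))
  expect_equal(unname(tmm_normalize(x_id)$tmm_factors), c(1, 1))
  # pure depth difference -> still unit factors
  x_depth <- toy_counts(cbind(base, 2 * base))
  expect_equal(unname(tmm_normalize(x_depth)$tmm_factors), c(1, 1),
               tolerance = 1e-12)
  # composition-biased block shifts the factor; matches the literal recipe
  biased <- base
  biased[1:8] <- biased[1:8] * 12
  x_bias <- toy_counts(cbind(base, biased))
  f <- tmm_normalize(x_bias)$tmm_factors
  expect_equal(unname(f), oracle_tmm_factors(cbind(base, biased)),
               tolerance = 1e-10)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-8)
  # a multi-sample matrix against the oracle, plus permutation equivariance
  m <- matrix(rpois(50 * 5, 40) + 1, ncol = 5)
  m[1:6, 3] <- m[1:6, 3] * 20
  expect_equal(unname(tmm_normalize(toy_counts(m))$tmm_factors),
               oracle_tmm_factors(m), tolerance = 1e-10)
  perm <- c(3, 1, 5, 2, 4)
  f_perm <- tmm_normalize(toy_counts(m[, perm]))$tmm_factors
  expect_equal(unname(f_perm),
               unname(tmm_normalize(toy_counts(m))$tmm_factors[perm]),
               tolerance = 1e-12)
  # log2 values are CPM on effective library sizes with +0.5 offset
  ex <- tmm_normalize(toy_counts(m))
  eff <- colSums(m) * ex$tmm_factors
  expect_equal(unname(ex$values),
               unname(log2(sweep(m, 2, eff, "/") * 1e6 + 0.5)))
})

test_that("expression bins follow left-open right-closed edges", {
  r <- matrix(c(0, 0.001, 5, 5.0001, 50, 50.01), nrow = 1)
  b <- bin_expression(r)
  expect_equal(as.vector(b),
               c("not_expressed", "low", "low", "moderate", "moderate",
                 "high"))
  set.seed(5)
  rr <- matrix(round(runif(60, 0, 80), 2), nrow = 6)
  bb <- bin_expression(rr)
  brute <- ifelse(rr == 0, "not_expressed",
                  ifelse(rr <= 5, "low", ifelse(rr <= 50, "moderate", "high")))
  expect_equal(bb, brute, ignore_attr = TRUE)
  # six-bin variant and validation
  b6 <- bin_expression(rr, edges = c(1, 5, 10, 50, 100),
                       labels = paste0("b", 1:6))
  expect_equal(sum(table(b6)), 60)
  expect_error(bin_expression(rr, edges = c(5, 5)), "increasing")
  expect_error(bin_expression(-rr), "non-negative")
})

test_that("core genes are those detected on every day", {
  m <- rbind(g1 = c(5, 2, 8, 1), g2 = c(5, 0, 8, 9), g3 = c(0, 0, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  x <- coex_counts(m, rep(500L, 3),
                   data.frame(sample_id = colnames(m), day = c(1, 1, 2, 3)))
  expect_equal(core_genes(x), c("g1", "g2"))  # g2 rescued by replicate on day 1
  expect_equal(core_genes(x, min_detect = 2), "g2")
  expect_setequal(core_genes(x, min_detect = 0), c("g1", "g2", "g3"))
  # planted: background zeroed on one whole day drops out of the core set
  sim <- simulate_counts(sim_config(n_genes = 120, module_sizes = 30,
                                    trajectory_kind = "early_high", seed = 4))
  cm <- sim$counts
  bg <- which(sim$truth$module == 0)
  cm$counts[bg, cm$sample_meta$day == 5] <- 0L
  expect_setequal(core_genes(cm), rownames(cm$counts)[-bg])
})

test_that("completeness summary reproduces the published arithmetic", {
  ceg <- completeness_summary(complete = 235, partial = 10, missing = 3)
  expect_equal(ceg$recovered_pct, 98.79)
  expect_equal(ceg$total, 248)
  busco <- completeness_summary(complete = 1128 + 549, fragmented = 517,
                                missing = 481)
  expect_equal(busco$recovered_pct, 82.02)
  expect_equal(completeness_summary(complete = 0, missing = 10)$recovered_pct,
               0)
  expect_error(completeness_summary(0, 0, 0, 0), "non-zero")
  expect_error(completeness_summary(-1, 5), "non-negative")
})
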