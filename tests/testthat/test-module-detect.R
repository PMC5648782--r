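test_that("average linkage matches a brute-force agglomeration oracle", {
  # two clean blocks: final merge at the between-block dissimilarity
  d <- make_block_diss(c(3, 3), within = 0, between = 1)
  hc <- hclust_average(d)
  expect_equal(max(hc$height), 1)
  # random 6-leaf dissimilarities: cophenetic distances agree exactly
  set.seed(31)
  for (rep in 1:4) {
    x <- matrix(rnorm(6 * 4), nrow = 6)
    dd <- as.matrix(dist(x))
    hc <- hclust_average(dd)
    expect_equal(unname(as.matrix(cophenetic(hc))),
                 oracle_linkage_cophenetic(dd, "average"), tolerance = 1e-12)
  }
  # permuting leaves permutes the tree isomorphically
  dd <- as.matrix(dist(matrix(rnorm(7 * 3), nrow = 7)))
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  c1 <- as.matrix(cophenetic(hclust_average(dd)))
  c2 <- as.matrix(cophenetic(hclust_average(dd[perm, perm])))
  expect_equal(unname(c2), unname(c1[perm, perm]), tolerance = 1e-12)
  dd[1, 2] <- NA
  expect_error(hclust_average(dd), "NA")
})

test_that("dynamic cut recovers clean planted blocks whole", {
  d <- make_block_diss(c(100, 100, 100), within = 0.1, between = 1)
  lab <- cut_dynamic(hclust_average(d), min_module_size = 50)
  expect_equal(sort(unique(lab)), 1:3)
  expect_equal(sum(lab == 0), 0)
  expect_true(all(table(lab, rep(1:3, each = 100)) %in% c(0, 100)))
  # min size larger than any branch -> everything unassigned
  expect_true(all(cut_dynamic(hclust_average(d), min_module_size = 150) == 0))
  expect_error(cut_dynamic(hclust_average(d), min_module_size = 400),
               "exceeds")
})

test_that("dynamic cut leaves unstructured dissimilarity unassigned", {
  set.seed(17)
  x <- matrix(rnorm(300 * 15), nrow = 300)
  net <- tom_similarity(adjacency_signed_hybrid(bicor_matrix(x), 8))
  lab <- cut_dynamic(hclust_average(net$diss_tom))
  expect_lte(mean(lab > 0), 0.10)
})

test_that("module eigengenes summarize their genes with the right orientation", {
  set.seed(12)
  profile <- rnorm(10)
  m <- matrix(rep(profile, each = 6), nrow = 6) *
    rep(c(2, 1, 3, 1, 2, 1), 10)                       # same shape, scales
  me <- module_eigengenes(m, rep(1L, 6))
  expect_equal(me$var_explained[["ME1"]], 1)
  expect_equal(abs(cor(me$eigengenes[1, ], profile)), 1)
  expect_gte(cor(me$eigengenes[1, ], profile), 0)       # oriented upward
  # flipping every member flips the eigengene back to the same orientation
  me_flip <- module_eigengenes(-m, rep(1L, 6))
  expect_gte(mean(cor(me_flip$eigengenes[1, ], t(-m))), 0)
  # unit norm per convention
  expect_equal(sum(me$eigengenes[1, ]^2), 1)
  # constant member genes are excluded with a warning
  m2 <- rbind(m, 5)
  expect_warning(module_eigengenes(m2, rep(1L, 7)), "constant")
})

test_that("planted module eigengenes track the planted trajectories", {
  sim <- simulate_counts(sim_config(seed = 6))
  expr <- filter_variance(tmm_normalize(filter_abundance(sim$counts)))
  truth <- sim$truth$module[rownames(expr$values)]
  me <- module_eigengenes(expr, truth)
  for (m in 1:3) {
    expect_gte(abs(cor(me$eigengenes[paste0("ME", m), ],
                       sim$truth$trajectories[m, ])), 0.95)
  }
})

test_that("modules merge exactly when eigengene correlation crosses the threshold", {
  set.seed(23)
  n <- 16
  base <- rnorm(n)
  # five modules: 1-2 nearly identical, 3 close to them, 4 and 5 independent
  traj <- rbind(base,
                base + rnorm(n, sd = 0.05),
                base + rnorm(n, sd = 0.3),
                rnorm(n),
                rnorm(n))
  genes <- do.call(rbind, lapply(1:5, function(m)
    matrix(rep(traj[m, ], each = 10), nrow = 10) + rnorm(10 * n, sd = 0.02)))
  labels <- rep(1:5, each = 10)
  me <- module_eigengenes(genes, labels)
  cm <- cor(t(me$eigengenes))
  merged <- merge_modules(genes, labels, me_diss_threshold = 0.1)
  # brute-force transitive closure of "1 - cor < 0.1"
  link <- cm > 0.9
  groups <- seq_len(5)
  repeat {
    changed <- FALSE
    for (i in 1:5) for (j in 1:5) {
      if (link[i, j] && groups[i] != groups[j]) {
        groups[groups == max(groups[i], groups[j])] <-
          min(groups[i], groups[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  expect_equal(length(unique(merged$labels)), length(unique(groups)))
  same_truth <- outer(groups, groups, "==")[rep(1:5, each = 10),
                                            rep(1:5, each = 10)]
  same_found <- outer(merged$labels, merged$labels, "==")
  expect_true(all(same_truth == same_found))
  # merging is idempotent at its fixed point
  again <- merge_modules(genes, merged$labels, me_diss_threshold = 0.1)
  expect_equal(again$n_modules, merged$n_modules)
  expect_equal(unname(again$labels), unname(merged$labels))
  # orthogonal trajectories never merge
  expect_gte(merged$n_modules, 3)
})

test_that("module-trait correlation gives exact r, t-based p, and BH fdr", {
  set.seed(8)
  day <- c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 8, 9)
  me <- rbind(ME1 = as.numeric(scale(day)), ME2 = rnorm(15), ME3 = rnorm(15))
  colnames(me) <- paste0("s", 1:15)
  traits <- data.frame(sample_id = colnames(me), day = day,
                       noise = rnorm(15))
  mt <- module_trait_cor(me, traits)
  r_day <- mt$table[mt$table$module == "ME1" & mt$table$trait == "day", ]
  expect_equal(r_day$r, 1)
  expect_lt(r_day$p, 1e-10)
  # p equals the closed-form t transform, fdr equals the step-up oracle
  expect_equal(mt$table$p,
               cor_pvalue(mt$table$r, 15), tolerance = 1e-12)
  for (tr in c("day", "noise")) {
    rows <- mt$table$trait == tr
    expect_equal(mt$table$fdr[rows], oracle_bh(mt$table$p[rows]),
                 tolerance = 1e-12)
  }
  # at this study size, a strong association (r = 0.87, n = 15) sits near 2.6e-5
  t_star <- 0.87 * sqrt(13 / (1 - 0.87^2))
  expect_equal(cor_pvalue(0.87, 15), 2 * pt(t_star, 13, lower.tail = FALSE))
  expect_equal(cor_pvalue(0.87, 15), 2.6e-5, tolerance = 0.02)
  # constant trait reported as missing, with a warning
  traits$flat <- 1
  expect_warning(mt2 <- module_trait_cor(me, traits), "constant")
  expect_true(all(is.na(mt2$table$r[mt2$table$trait == "flat"])))
})

test_that("raw module-trait p-values are uniform under the null", {
  set.seed(99)
  me <- matrix(rnorm(2000 * 15), nrow = 2000)
  colnames(me) <- paste0("s", 1:15)
  traits <- data.frame(sample_id = colnames(me), t1 = rnorm(15))
  mt <- module_trait_cor(me, traits)
  expect_equal(mean(mt$table$p < 0.05), 0.05, tolerance = 0.02)
})

test_that("kME and the hub rule behave at the documented boundary", {
  set.seed(3)
  n <- 15
  me <- rbind(ME1 = rnorm(n))
  colnames(me) <- paste0("s", 1:n)
  x <- rbind(g_same = me[1, ], g_noise = rnorm(n))
  k <- kme(x, me)
  expect_equal(k$kme["g_same", "ME1"], 1)
  expect_equal(k$p["g_same", "ME1"], 0)
  # kME = 0.9 at n = 15 has p ~ 4.9e-6 > 1e-6: not a hub under the joint rule
  expect_equal(cor_pvalue(0.9, 15), 4.9e-6, tolerance = 0.02)
  hubs <- hub_genes(k, c(1L, 1L))
  expect_equal(hubs$gene, "g_same")
  # a background gene almost never reaches kME > 0.9 against a planted module
  sim <- simulate_counts(sim_config(n_genes = 1200, module_sizes = 100,
                                    trajectory_kind = "early_high",
                                    seed = 13))
  expr <- tmm_normalize(sim$counts)
  truth <- sim$truth$module
  me_p <- module_eigengenes(expr, truth)
  kk <- kme(expr, me_p)
  bg <- names(truth)[truth == 0]
  expect_lte(mean(kk$kme[bg, "ME1"] > 0.9, na.rm = TRUE), 0.01)
})
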