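make_annot <- function(terms) {
  tibble::tibble(
    gene = unlist(terms),
    term = rep(names(terms), lengths(terms))
  )
}

test_that("hypergeometric over-representation matches the closed-form tail", {
  universe <- paste0("g", 1:100)
  annot <- make_annot(list(
    hit = paste0("g", 1:10),
    broad = paste0("g", 1:50),
    off = paste0("g", 91:100)
  ))
  res <- overrepresentation(paste0("g", 1:10), universe, annot)
  tab <- res$table
  p_hit <- tab$p[tab$term == "hit"]
  expect_equal(p_hit, oracle_hyper_tail(10, 10, 100, 10), tolerance = 1e-12)
  expect_equal(p_hit, min(tab$p))
  # a term disjoint from the test set has one-sided p = 1
  expect_equal(tab$p[tab$term == "off"], 1)
  # BH across terms matches the step-up oracle
  expect_equal(tab$p_adj, oracle_bh(tab$p), tolerance = 1e-15)
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  expect_error(overrepresentation(character(0), universe, annot), "empty")
  expect_error(overrepresentation("gX", universe, annot), "subset")
})

test_that("hypergeometric p equals exhaustive tail enumeration on small universes", {
  set.seed(55)
  for (rep in 1:10) {
    N <- sample(20:50, 1)
    universe <- paste0("g", seq_len(N))
    term_genes <- sample(universe, sample(3:(N - 5), 1))
    test_set <- sample(universe, sample(3:15, 1))
    annot <- make_annot(list(t1 = term_genes))
    res <- overrepresentation(test_set, universe, annot)
    x <- sum(test_set %in% term_genes)
    expect_equal(res$table$p[1],
                 oracle_hyper_tail(x, length(term_genes), N,
                                   length(test_set)),
                 tolerance = 1e-12)
  }
})

test_that("random test sets produce ~5% raw positives", {
  set.seed(77)
  universe <- paste0("g", 1:400)
  annot <- make_annot(setNames(
    lapply(1:25, function(i) sample(universe, 80)), paste0("t", 1:25)))
  hits <- replicate(60, {
    res <- overrepresentation(sample(universe, 120), universe, annot)
    mean(res$table$p < 0.05)
  })
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("Wallenius reduces to the central test for constant lengths", {
  universe <- paste0("g", 1:60)
  annot <- make_annot(list(t1 = paste0("g", 1:12),
                           t2 = paste0("g", 30:60)))
  test_set <- paste0("g", c(1:8, 40:45))
  lengths <- rep(1000, 60)
  central <- overrepresentation(test_set, universe, annot)
  wal <- wallenius_test(test_set, universe, annot, lengths)
  for (tm in c("t1", "t2")) {
    expect_equal(wal$table$p[wal$table$term == tm],
                 central$table$p[central$table$term == tm],
                 tolerance = 1e-6)
  }
})

test_that("Wallenius is more conservative for a length-confounded term", {
  set.seed(88)
  N <- 300
  universe <- paste0("g", 1:N)
  lengths <- sort(round(exp(rnorm(N, log(1500), 0.7))))
  # selection strongly biased towards long genes
  prob <- lengths / max(lengths)
  sel <- universe[runif(N) < prob * 0.5]
  long_term <- universe[201:300]        # the longest genes
  annot <- make_annot(list(long = long_term,
                           rand = sample(universe, 100)))
  central <- overrepresentation(sel, universe, annot)
  wal <- wallenius_test(sel, universe, annot, lengths)
  expect_gt(wal$table$p[wal$table$term == "long"],
            central$table$p[central$table$term == "long"])
  expect_gt(wal$table$odds[wal$table$term == "long"], 1)
  # single-term universe stays well-defined
  one <- wallenius_test(sel, universe, make_annot(list(only = long_term)),
                        lengths)
  expect_true(one$table$p > 0 && one$table$p <= 1)
  expect_error(wallenius_test(universe, universe, annot, lengths), "universe")
})

test_that("slim rollup tallies significant terms deterministically", {
  universe <- paste0("g", 1:100)
  annot <- make_annot(list(a = paste0("g", 1:10), b = paste0("g", 1:12),
                           c = paste0("g", 50:100)))
  res <- overrepresentation(paste0("g", 1:10), universe, annot)
  slim <- data.frame(term = c("a", "b", "c"),
                     category = c("growth", "growth", "transport"))
  roll <- slim_rollup(res, slim)
  sig <- res$table$term[res$table$significant]
  expect_equal(roll$n_significant[roll$category == "growth"],
               sum(sig %in% c("a", "b")))
  expect_equal(sum(roll$n_significant), length(sig))
  # unmapped significant terms land in "other"
  roll2 <- slim_rollup(res, slim[slim$term != "a", ])
  if ("a" %in% sig) {
    expect_equal(roll2$n_significant[roll2$category == "other"], 1)
  }
  # no significant terms -> all-zero tally
  res0 <- overrepresentation(sample(universe, 10), universe,
                             make_annot(list(z = sample(universe, 50))),
                             alpha = 1e-12)
  roll0 <- slim_rollup(res0, slim)
  expect_true(all(roll0$n_significant == 0))
  # random mapping equals a brute-force tally
  set.seed(4)
  slim_r <- data.frame(term = c("a", "b", "c"),
                       category = sample(c("x", "y"), 3, replace = TRUE))
  roll_r <- slim_rollup(res, slim_r)
  for (cc in unique(slim_r$category)) {
    expect_equal(roll_r$n_significant[roll_r$category == cc],
                 sum(sig %in% slim_r$term[slim_r$category == cc]))
  }
})
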