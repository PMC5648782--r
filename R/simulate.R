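#' Configuration for the staged co-expression count simulator
#'
#' Describes a bulk RNA-seq time course of single embryos with planted
#' co-expression modules. Defaults emulate a 15-library design covering nine
#' consecutive embryonic days (days 1-6 with two replicate embryos `a`/`b`,
#' days 7-9 with one), three planted modules whose eigengene trajectories
#' follow the three canonical temporal shapes of staged embryogenesis
#' (high early / high late / switching at mid-development), and 2,000
#' unstructured background genes.
#'
#' @param n_genes total number of genes, planted modules included.
#' @param stage_of_sample integer day label per sample; its length sets the
#'   number of samples.
#' @param module_sizes integer vector of planted module sizes (may be empty);
#'   `sum(module_sizes) <= n_genes`.
#' @param trajectory_kind one of `"early_high"`, `"late_high"`,
#'   `"mid_switch"`, `"covariate_linked"`, `"flat"` per module.
#'   `covariate_linked` ties the module to a hidden binary (sex-like) sample
#'   covariate instead of the day.
#' @param loading_mean,loading_sd mean and spread of the per-gene loading on
#'   the module trajectory (natural-log units per trajectory SD).
#' @param baseline_log_mean,baseline_log_sd location and spread of per-gene
#'   baseline log expression (natural log of expected counts at the default
#'   library size).
#' @param nb_dispersion negative-binomial dispersion `alpha`
#'   (variance `mu + alpha * mu^2`).
#' @param libsize_range range the per-sample expected library sizes are drawn
#'   from (uniform).
#' @param length_range_bp range gene lengths (bp) are drawn from (uniform).
#' @param covariate_effect log-scale offset applied to covariate-linked genes
#'   in samples with hidden covariate = 1 (scaled by the gene loading).
#' @param clade_boundary_day last day of the "early" clade; the clade trait is
#'   `1(day >= clade_boundary_day + 1)`.
#' @param seed integer seed; identical seeds give bit-identical simulations.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = 2300,
                       stage_of_sample = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 7, 8, 9),
                       module_sizes = c(100, 100, 100),
                       trajectory_kind = c("early_high", "late_high", "mid_switch"),
                       loading_mean = 1.0,
                       loading_sd = 0.25,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1.0,
                       nb_dispersion = 0.1,
                       libsize_range = c(8e5, 1.2e6),
                       length_range_bp = c(300L, 3000L),
                       covariate_effect = 1.0,
                       clade_boundary_day = 5L,
                       seed = 1L) {
  kinds <- c("early_high", "late_high", "mid_switch", "covariate_linked", "flat")
  if (length(module_sizes) != length(trajectory_kind)) {
    stop_coex("module_sizes and trajectory_kind must have equal length")
  }
  if (length(module_sizes) && any(module_sizes < 1)) {
    stop_coex("module sizes must be positive")
  }
  if (sum(module_sizes) > n_genes) {
    stop_coex("sum(module_sizes) exceeds n_genes")
  }
  if (!all(trajectory_kind %in% kinds)) {
    stop_coex(paste0("trajectory_kind must be one of: ",
                     paste(kinds, collapse = ", ")))
  }
  if (sum(trajectory_kind == "covariate_linked") > 1) {
    stop_coex("at most one covariate_linked module is supported")
  }
  if (nb_dispersion <= 0) stop_coex("nb_dispersion must be positive")
  if (loading_sd <= 0) stop_coex("loading_sd must be positive")
  if (length(libsize_range) != 2 || any(libsize_range <= 0) ||
      diff(libsize_range) < 0) {
    stop_coex("libsize_range must be an increasing pair of positive numbers")
  }
  if (length(length_range_bp) != 2 || any(length_range_bp <= 0) ||
      diff(length_range_bp) < 0) {
    stop_coex("length_range_bp must be an increasing pair of positive numbers")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         stage_of_sample = as.integer(stage_of_sample),
         module_sizes = as.integer(module_sizes),
         trajectory_kind = trajectory_kind,
         loading_mean = loading_mean, loading_sd = loading_sd,
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         nb_dispersion = nb_dispersion,
         libsize_range = libsize_range,
         length_range_bp = length_range_bp,
         covariate_effect = covariate_effect,
         clade_boundary_day = as.integer(clade_boundary_day),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Logistic ramps over day, standardized across the sample vector. Shapes
# mirror the canonical temporal clusters of staged embryogenesis:
# early_high is U-shaped (high before mid-development, dip after the
# mid-embryogenesis switch, partial late recovery), mid_switch turns on at
# mid-development and off again late (antagonistic to early_high), and
# late_high rises monotonically towards hatching.
module_trajectory <- function(kind, day, covariate) {
  raw <- switch(kind,
    early_high = 1 / (1 + exp((day - 4.5) / 0.7)) +
      0.35 / (1 + exp(-(day - 8) / 0.7)),
    late_high  = 1 / (1 + exp(-(day - 6.5) / 1.2)),
    mid_switch = 1 / (1 + exp(-(day - 4.7) / 0.35)) -
      1 / (1 + exp(-(day - 6.8) / 0.35)),
    covariate_linked = as.numeric(covariate),
    flat = rep(0, length(day))
  )
  if (sd(raw) == 0) return(raw)
  as.numeric(scale(raw))
}

#' Simulate a staged count matrix with planted co-expression modules
#'
#' Generates a genes x samples negative-binomial count matrix in which each
#' planted module shares a standardized eigengene trajectory over the
#' embryonic days: gene g in module m has log expected relative expression
#' `baseline_g + loading_g * trajectory_m(sample)`, background genes are
#' flat, expected counts are scaled to the sample's library size, and counts
#' are drawn NB with variance `mu + alpha mu^2`. One module may instead track
#' a hidden binary covariate (a sex-like factor never exposed as a trait).
#'
#' All randomness flows from `config$seed`: the generator is seeded once and
#' draws in a fixed documented order (library sizes, hidden covariate, gene
#' lengths, baselines, loadings, then counts), so identical configs are
#' bit-identical.
#'
#' @param config a [sim_config()].
#' @return a list with `counts` (a [coex_counts()]) and `truth`
#'   (class `coex_truth`: `module` gene labels with 0 = background,
#'   `trajectories` modules x samples standardized matrix, `covariate`
#'   hidden 0/1 vector per sample, `loadings`, `log_mu` the expected
#'   log relative expression).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_g <- config$n_genes
  day <- config$stage_of_sample
  n_s <- length(day)
  gene_ids <- sprintf("g%04d", seq_len(n_g))
  sample_ids <- make.unique(paste0("d", day), sep = "_")

  # draw order is part of the reproducibility contract
  lib_size <- runif(n_s, config$libsize_range[1], config$libsize_range[2])
  covariate <- as.integer(sample(rep(c(0L, 1L), length.out = n_s)))
  gene_length <- round(runif(n_g, config$length_range_bp[1],
                             config$length_range_bp[2]))
  baseline <- rnorm(n_g, config$baseline_log_mean, config$baseline_log_sd)

  n_mod <- length(config$module_sizes)
  module <- integer(n_g)
  if (n_mod > 0) {
    module[seq_len(sum(config$module_sizes))] <-
      rep(seq_len(n_mod), times = config$module_sizes)
  }
  loading <- numeric(n_g)
  in_mod <- module > 0
  loading[in_mod] <- rnorm(sum(in_mod), config$loading_mean, config$loading_sd)

  traj <- matrix(0, nrow = max(n_mod, 0), ncol = n_s,
                 dimnames = list(if (n_mod) paste0("M", seq_len(n_mod)),
                                 sample_ids))
  if (n_mod > 0) {
    for (m in seq_len(n_mod)) {
      kind <- config$trajectory_kind[m]
      tr <- module_trajectory(kind, day, covariate)
      if (kind == "covariate_linked") {
        # binary offset on log-mean, standardized like the other trajectories
        tr <- as.numeric(scale(covariate)) * config$covariate_effect
      }
      traj[m, ] <- tr
    }
  }

  log_mu <- matrix(baseline, nrow = n_g, ncol = n_s)
  if (n_mod > 0) {
    for (m in seq_len(n_mod)) {
      idx <- which(module == m)
      log_mu[idx, ] <- log_mu[idx, ] + outer(loading[idx], traj[m, ])
    }
  }
  rel <- exp(log_mu)
  rel <- sweep(rel, 2, colSums(rel), "/")
  mu <- sweep(rel, 2, lib_size, "*")
  counts <- matrix(rnbinom(n_g * n_s, mu = mu, size = 1 / config$nb_dispersion),
                   nrow = n_g, ncol = n_s,
                   dimnames = list(gene_ids, sample_ids))

  meta <- tibble(
    sample_id = sample_ids,
    day = day,
    individual = as.integer(stats::ave(day, day, FUN = seq_along) - 1L),
    clade = as.integer(day >= config$clade_boundary_day + 1L)
  )
  truth <- structure(
    list(module = setNames(module, gene_ids),
         trajectories = traj,
         covariate = setNames(covariate, sample_ids),
         loadings = setNames(loading, gene_ids),
         log_mu = log_mu,
         config = config),
    class = "coex_truth"
  )
  list(counts = coex_counts(counts, gene_length, meta), truth = truth)
}

#' Build the sample trait table from a simulation
#'
#' Returns the traits used for module-trait correlation: numeric `day`,
#' binary `clade` (thresholded at the configured boundary day), binary
#' `individual` (replicate a/b within a day). The hidden covariate is
#' withheld by default — it exists only in the planted truth, mimicking an
#' unrecorded factor such as embryo sex.
#'
#' @param config a [sim_config()].
#' @param truth the `coex_truth` returned by [simulate_counts()].
#' @param withhold_covariate if `FALSE`, the hidden covariate is exposed as a
#'   fourth trait column `covariate`.
#' @return a tibble with `sample_id` plus one numeric column per trait.
#' @export
simulate_traits <- function(config, truth, withhold_covariate = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "coex_truth"))
  if (length(truth$covariate) != length(config$stage_of_sample)) {
    stop_coex("truth is inconsistent with config")
  }
  day <- config$stage_of_sample
  out <- tibble(
    sample_id = names(truth$covariate),
    day = as.numeric(day),
    clade = as.numeric(day >= config$clade_boundary_day + 1L),
    individual = as.numeric(stats::ave(day, day, FUN = seq_along) - 1)
  )
  if (!withhold_covariate) out$covariate <- as.numeric(truth$covariate)
  out
}

#' @export
print.coex_truth <- function(x, ...) {
  cat("<coex_truth> ", length(x$module), " genes, ",
      nrow(x$trajectories), " planted modules (",
      paste(x$config$trajectory_kind, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
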