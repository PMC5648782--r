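#' Pipeline configuration
#'
#' Collects every stage parameter in one validated list. Unknown keys are
#' rejected. Either supply `counts` (a [coex_counts()] or a counts TSV path
#' written by [write_counts_tsv()]) or leave it `NULL` to simulate from
#' `sim` (a [sim_config()]).
#'
#' @param ... named overrides of the defaults listed below.
#' @return a validated `coex_config` list.
#' @export
coex_config <- function(...) {
  defaults <- list(
    counts = NULL,             # coex_counts, path, or NULL -> simulate
    sim = sim_config(),
    traits = NULL,             # data frame; NULL -> simulate_traits()
    annotation = NULL,         # data frame gene/term; NULL -> skip enrichment
    slim_map = NULL,
    min_count = 5,
    var_factor = 2.0,
    var_stat = "mean",
    trim_m = 0.30,
    trim_a = 0.05,
    max_poutliers = 0.1,
    power = NULL,              # NULL -> scale-free selection
    powers = 1:30,
    target_r2 = 0.85,
    min_module_size = 50,
    deep_split = 2,
    me_diss_threshold = 0.1,
    kme_r_min = 0.9,
    kme_p_max = 1e-6,
    scan_alpha = 0.01,
    scan_family = "partitions_x_modules",
    boot_b = 1000,
    boot_scales = seq(0.5, 1.4, by = 0.1),
    enrich_alpha = 0.05,
    max_genes = 5000,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_coex(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  structure(cfg, class = "coex_config")
}

#' Run the full co-expression pipeline
#'
#' Executes simulate (when no counts are supplied) -> abundance filter ->
#' TMM normalization -> variance filter -> signed-hybrid network ->
#' dynamic branch cut -> eigengene merging -> module-trait correlation ->
#' kME/hub genes -> exhaustive bipartition scan -> bootstrap sample
#' clustering -> MDS -> (optional) over-representation analysis, writing
#' every intermediate artifact plus a machine-readable `summary.json` into
#' `out_dir`. Identical config and seed give an identical summary.
#'
#' @param config a [coex_config()].
#' @param out_dir run directory (created); `NULL` keeps everything in
#'   memory only.
#' @param verbose emit one log line per stage (stage name, seed, elapsed
#'   seconds).
#' @return a `coex_run` list with every stage result and `summary`.
#' @export
run_pipeline <- function(config = coex_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "coex_config"))
  t_start <- Sys.time()
  log_stage <- function(stage) {
    if (verbose) {
      message(sprintf("[coexmod] stage=%s seed=%s elapsed=%.1fs", stage,
                      config$seed,
                      as.numeric(Sys.time() - t_start, units = "secs")))
    }
  }
  truth <- NULL
  if (is.null(config$counts)) {
    sim <- simulate_counts(config$sim)
    counts <- sim$counts
    truth <- sim$truth
  } else if (is.character(config$counts)) {
    counts <- read_counts_tsv(config$counts)
  } else {
    counts <- config$counts
  }
  traits <- config$traits
  if (is.null(traits) && !is.null(truth)) {
    traits <- simulate_traits(config$sim, truth)
  }

  log_stage("input")
  n_input <- nrow(counts$counts)
  counts_f <- filter_abundance(counts, min_count = config$min_count)
  expr <- tmm_normalize(counts_f, trim_M = config$trim_m,
                        trim_A = config$trim_a)
  expr <- filter_variance(expr, factor = config$var_factor,
                          stat = config$var_stat)

  log_stage("preprocess")
  net <- build_network(expr, beta = config$power,
                       maxPOutliers = config$max_poutliers,
                       powers = config$powers, target_R2 = config$target_r2,
                       max_genes = config$max_genes)
  log_stage("network")
  dend <- hclust_average(net$diss_tom)
  raw_labels <- cut_dynamic(dend, min_module_size = config$min_module_size,
                            deep_split = config$deep_split)
  modules <- if (any(raw_labels > 0)) {
    merge_modules(expr, raw_labels,
                  me_diss_threshold = config$me_diss_threshold)
  } else {
    NULL
  }

  log_stage("modules")
  mt <- scan <- kme_obj <- hubs <- NULL
  if (!is.null(modules)) {
    if (!is.null(traits)) mt <- module_trait_cor(modules, traits)
    scan <- scan_partitions(modules, alpha = config$scan_alpha,
                            family = config$scan_family)
    kme_obj <- kme(expr, modules)
    hubs <- hub_genes(kme_obj, modules$labels,
                      r_min = config$kme_r_min, p_max = config$kme_p_max)
  }
  log_stage("traits-scan")
  boot <- multiscale_bootstrap(expr, scales = config$boot_scales,
                               B = config$boot_b, seed = config$seed)
  mds <- classical_mds(sample_cor_dist(expr))

  log_stage("boot-mds")
  enrich <- NULL
  if (!is.null(config$annotation) && !is.null(hubs) && nrow(hubs) > 0) {
    enrich <- overrepresentation(hubs$gene, rownames(expr$values),
                                 config$annotation,
                                 alpha = config$enrich_alpha)
  }

  log_stage("enrich")
  ari <- NULL
  if (!is.null(truth) && !is.null(modules)) {
    ari <- adjusted_rand_index(truth$module[rownames(expr$values)],
                               modules$labels)
  }

  summary <- list(
    n_genes_input = n_input,
    n_after_abundance = nrow(counts_f$counts),
    n_after_variance = nrow(expr$values),
    beta = net$beta,
    scale_free_r2 = if (!is.null(net$sft))
      net$sft$fit$r_squared[net$sft$fit$power == net$beta] else NA,
    n_modules_pre_merge = if (!is.null(modules)) modules$n_pre_merge else 0L,
    n_modules = if (!is.null(modules)) modules$n_modules else 0L,
    n_unassigned = if (!is.null(modules)) sum(modules$labels == 0)
      else nrow(expr$values),
    n_hub_genes = if (!is.null(hubs)) nrow(hubs) else 0L,
    n_significant_module_trait = if (!is.null(mt))
      sum(mt$table$fdr < 0.05, na.rm = TRUE) else NA,
    flagged_partitions = if (!is.null(scan))
      sum(scan$table$flagged) else NA,
    max_cluster_au = max(boot$table$au),
    adjusted_rand_index = ari,
    n_significant_terms = if (!is.null(enrich))
      sum(enrich$table$significant) else NA,
    seed = config$seed
  )

  run <- structure(
    list(config = config, counts = counts, truth = truth, traits = traits,
         expr = expr, network = net, dendrogram = dend,
         raw_labels = raw_labels, modules = modules, module_trait = mt,
         scan = scan, kme = kme_obj, hubs = hubs, boot = boot, mds = mds,
         enrichment = enrich, summary = summary),
    class = "coex_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  cfg <- run$config
  snapshot <- cfg[!vapply(cfg, is.object, logical(1))]
  snapshot <- snapshot[!vapply(snapshot, is.data.frame, logical(1))]
  yaml::write_yaml(snapshot, p("config.yaml"))
  write_counts_tsv(run$counts, p("counts.tsv"))
  if (!is.null(run$truth)) write_truth_json(run$truth, p("truth.json"))
  if (!is.null(run$traits)) {
    write.table(run$traits, p("traits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_matrix_tsv(run$expr, p("expression.tsv"))
  jsonlite::write_json(run$expr$filter_log, p("filter_log.json"),
                       auto_unbox = TRUE)
  if (!is.null(run$modules)) {
    write.table(tidy(run$modules), p("modules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_matrix_tsv(run$modules$eigengenes, p("eigengenes.tsv"))
  }
  if (!is.null(run$module_trait)) {
    write.table(run$module_trait$table, p("module_trait.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$scan)) {
    write.table(run$scan$table, p("partition_scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$hubs)) {
    write.table(run$hubs, p("hub_genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write.table(run$boot$table, p("boot_support.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(run$boot, p("sample_dendrogram.nwk"))
  write.table(data.frame(sample = rownames(run$mds$points), run$mds$points),
              p("mds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$enrichment)) {
    write.table(run$enrichment$table, p("enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = 10, null = "null")
  invisible(out_dir)
}

#' @export
print.coex_run <- function(x, ...) {
  cat("<coex_run>\n")
  s <- x$summary
  cat("  genes: ", s$n_genes_input, " -> ", s$n_after_abundance,
      " (abundance) -> ", s$n_after_variance, " (variance)\n", sep = "")
  cat("  beta = ", s$beta, "; modules: ", s$n_modules_pre_merge, " -> ",
      s$n_modules, " after merging; ", s$n_hub_genes, " hub genes\n",
      sep = "")
  invisible(x)
}
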