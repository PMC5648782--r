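#' Tidy methods for coexmod results
#'
#' broom-style accessors: `tidy()` returns one row per element (gene, term,
#' cluster, module-trait pair, ...), `glance()` one summary row per object.
#'
#' @param x a coexmod result object.
#' @param ... unused.
#' @return a tibble.
#' @name coexmod_tidiers
NULL

#' @rdname coexmod_tidiers
#' @export
tidy.coex_sft <- function(x, ...) as_tibble(x$fit)

#' @rdname coexmod_tidiers
#' @export
glance.coex_sft <- function(x, ...) {
  tibble(power = x$power,
         r_squared = x$fit$r_squared[x$fit$power == x$power],
         mean_k = x$fit$mean_k[x$fit$power == x$power],
         target_R2 = x$target_R2)
}

#' @rdname coexmod_tidiers
#' @export
tidy.coex_modules <- function(x, ...) {
  tibble(gene = names(x$labels) %||% as.character(seq_along(x$labels)),
         module = as.integer(x$labels),
         pre_merge_module = as.integer(x$pre_merge_labels))
}

#' @rdname coexmod_tidiers
#' @export
glance.coex_modules <- function(x, ...) {
  tibble(n_modules = x$n_modules, n_pre_merge = x$n_pre_merge,
         n_unassigned = sum(x$labels == 0),
         largest = if (x$n_modules) max(tabulate(x$labels)) else 0L,
         me_diss_threshold = x$me_diss_threshold)
}

#' @rdname coexmod_tidiers
#' @export
tidy.coex_module_trait <- function(x, ...) as_tibble(x$table)

#' @rdname coexmod_tidiers
#' @export
glance.coex_module_trait <- function(x, ...) {
  tibble(n_modules = nrow(x$r), n_traits = ncol(x$r), n = x$n,
         n_significant = sum(x$fdr < 0.05, na.rm = TRUE),
         adjust_family = x$adjust_family)
}

#' @rdname coexmod_tidiers
#' @export
tidy.coex_scan <- function(x, ...) as_tibble(x$table)

#' @rdname coexmod_tidiers
#' @export
glance.coex_scan <- function(x, ...) {
  tibble(n_modules = nrow(x$table), n_partitions = x$n_partitions,
         multiplier = x$multiplier, n_flagged = sum(x$table$flagged),
         alpha = x$alpha)
}

#' @rdname coexmod_tidiers
#' @export
tidy.coex_boot <- function(x, ...) as_tibble(x$table)

#' @rdname coexmod_tidiers
#' @export
glance.coex_boot <- function(x, ...) {
  tibble(n_clusters = nrow(x$table), B = x$B, n_scales = length(x$scales),
         min_au = min(x$table$au), max_au = max(x$table$au), seed = x$seed)
}

#' @rdname coexmod_tidiers
#' @export
tidy.coex_enrich <- function(x, ...) as_tibble(x$table)

#' @rdname coexmod_tidiers
#' @export
glance.coex_enrich <- function(x, ...) {
  tibble(n_terms = nrow(x$table), n_significant = sum(x$table$significant),
         n_test = x$n_test, n_universe = x$n_universe, method = x$method,
         alpha = x$alpha)
}

#' @rdname coexmod_tidiers
#' @export
tidy.coex_mds <- function(x, ...) {
  as_tibble(x$points, rownames = "sample_id")
}

#' @rdname coexmod_tidiers
#' @export
tidy.coex_kme <- function(x, ...) {
  as_tibble(x$kme, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "module", values_to = "kme") |>
    left_join(
      as_tibble(x$p, rownames = "gene") |>
        tidyr::pivot_longer(-"gene", names_to = "module", values_to = "p"),
      by = c("gene", "module"))
}
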