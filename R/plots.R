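#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result types: the scale-free
#' fit profile, the module-trait heatmap, eigengene trajectories, MDS
#' coordinates, and bootstrap support.
#'
#' @param object a coexmod result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name coexmod_plots
NULL

#' @rdname coexmod_plots
#' @export
autoplot.coex_sft <- function(object, ...) {
  df <- object$fit
  ggplot2::ggplot(df, ggplot2::aes(x = .data$power, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = object$target_R2, linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$power == object$power),
                        show.legend = FALSE) +
    ggplot2::labs(x = "soft-threshold power",
                  y = expression("signed scale-free fit" ~ R^2)) +
    ggplot2::theme_minimal()
}

#' @rdname coexmod_plots
#' @export
autoplot.coex_module_trait <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f\n(%.1g)", .data$r, .data$fdr)), size = 2.8) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#313695",
                                  mid = "white", high = "#a50026") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' @rdname coexmod_plots
#' @export
autoplot.coex_me <- function(object, ...) {
  df <- as_tibble(object$eigengenes, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "sample_id",
                        values_to = "eigengene") |>
    mutate(sample_id = factor(.data$sample_id,
                              levels = colnames(object$eigengenes)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$eigengene,
                                   group = .data$module,
                                   colour = .data$module)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample", y = "module eigengene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname coexmod_plots
#' @export
autoplot.coex_modules <- function(object, ...) {
  autoplot.coex_me(structure(list(eigengenes = object$eigengenes),
                             class = "coex_me"))
}

#' @rdname coexmod_plots
#' @export
autoplot.coex_mds <- function(object, ...) {
  df <- tidy(object)
  if (object$k_used < 2) stop_coex("need >= 2 recovered dimensions to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   label = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' @rdname coexmod_plots
#' @export
autoplot.coex_boot <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bp, y = .data$au,
                                   size = .data$size)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "bootstrap probability (BP)",
                  y = "approximately unbiased support (AU)",
                  size = "cluster size") +
    ggplot2::theme_minimal()
}
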