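# ggplot2 views of the main result types.

#' @rdname plot_manhattan
#' @param object An `rg_matrix`.
#' @param ... Unused.
#' @export
autoplot.rg_matrix <- function(object, ...) {
  df <- tidyr::expand_grid(trait1 = object$traits, trait2 = object$traits)
  df$rg <- as.vector(t(object$rg))
  ggplot2::ggplot(df, ggplot2::aes(.data$trait2, .data$trait1,
                                   fill = .data$rg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey85", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r_g",
                  title = "Pairwise genetic correlations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname plot_manhattan
#' @export
autoplot.scale_free_fit <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(log10(.data$mean_k),
                                            log10(.data$freq))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "#B2182B") +
    ggplot2::labs(
      x = "log10(k)", y = "log10(p(k))",
      title = sprintf("Scale-free topology fit (R² = %.2f)",
                      object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plots of association scan results
#'
#' `plot_manhattan()` draws the per-SNP `-log10(P)` of a module scan along
#' the genome with the genome-wide (5e-8) and module-threshold lines;
#' `plot_qq()` draws the expected-vs-observed QQ plot. Both accept the
#' output of [export_association_table()].
#'
#' @param tables A list with `association` and `qq` tibbles, as returned
#'   by [export_association_table()].
#' @param statistic `"S_HOM"` or `"S_HET"`.
#' @param threshold Module significance line (default 1e-7).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(tables, statistic = c("S_HOM", "S_HET"),
                           threshold = 1e-7) {
  statistic <- match.arg(statistic)
  assoc <- tables$association
  ycol <- if (statistic == "S_HOM") "LOG10P_HOM" else "LOG10P_HET"
  assoc$pos_index <- seq_len(nrow(assoc))
  ggplot2::ggplot(assoc, ggplot2::aes(.data$pos_index, .data[[ycol]],
                                      colour = factor(.data$CHR %% 2))) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(5e-8), linetype = "dashed",
                        colour = "#B2182B") +
    ggplot2::geom_hline(yintercept = -log10(threshold),
                        linetype = "dotted", colour = "#2166AC") +
    ggplot2::scale_colour_manual(values = c("grey30", "grey60")) +
    ggplot2::labs(x = "SNP (genome order)",
                  y = sprintf("-log10(P) [%s]", statistic),
                  title = "Cross-phenotype module scan") +
    ggplot2::theme_minimal()
}

#' @rdname plot_manhattan
#' @export
plot_qq <- function(tables) {
  ggplot2::ggplot(tables$qq, ggplot2::aes(.data$expected, .data$observed,
                                          colour = .data$statistic)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Expected -log10(P)", y = "Observed -log10(P)") +
    ggplot2::theme_minimal()
}
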