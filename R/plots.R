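#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PC1/PC2 scatter of inversion calls
#'
#' The tri-cluster view of the local genotype PCA: one point per
#' individual in the first two principal components, colored by called
#' inversion genotype. Excluded (ambiguous) individuals plot as crosses.
#'
#' @param object an `inversion_calls` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.inversion_calls <- function(object, ...) {
  df <- tidy.inversion_calls(object)
  g <- glance.inversion_calls(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                   color = .data$label,
                                   shape = .data$label == "EXCLUDED")) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                guide = "none") +
    ggplot2::labs(x = "PC1", y = "PC2", color = "genotype",
                  title = "Inversion genotypes from local SNP PCA",
                  subtitle = sprintf("H1/H1 %d, H1/H2 %d, H2/H2 %d, excluded %d; HWE p = %.2f",
                                     g$n_H1H1, g$n_H1H2, g$n_H2H2,
                                     g$n_excluded, g$hwe_p)) +
    ggplot2::theme_minimal()
}

#' Effect-size plot for an eQTL table
#'
#' Per-probe dosage effect B with its 95% CI; Bonferroni-significant
#' probes in color.
#'
#' @param object an `eqtl_table` from [run_cis_eqtl()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.eqtl_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$probe_id, .data$B),
                                   y = .data$B, color = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$CI_low,
                                          ymax = .data$CI_high)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "B (log2 expression per H1 copy)",
                  color = "Bonferroni\nsignificant") +
    ggplot2::theme_minimal()
}

#' Dosage-group expression plot
#'
#' Mean log2 expression (with SD error bars) per inversion genotype for
#' selected probes, the barplot view conventionally used to show an
#' allele-dosage effect.
#'
#' @param expr an [expression_table].
#' @param calls an `inversion_calls` tibble.
#' @param probe_ids probes to show (default: all, capped at 6).
#' @return a ggplot.
#' @export
plot_dosage_groups <- function(expr, calls, probe_ids = NULL) {
  if (is.null(probe_ids))
    probe_ids <- utils::head(expr$probe_meta$probe_id, 6)
  df <- tidy.expression_table(expr) |>
    dplyr::filter(.data$probe_id %in% probe_ids) |>
    dplyr::inner_join(tidy.inversion_calls(calls), by = "individual_id") |>
    dplyr::filter(.data$label != "EXCLUDED") |>
    dplyr::group_by(.data$probe_id, .data$label) |>
    dplyr::summarise(mean = mean(.data$expression),
                     sd = stats::sd(.data$expression), .groups = "drop")
  df$label <- factor(df$label, levels = c("H1H1", "H1H2", "H2H2"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$mean,
                                   fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~probe_id, scales = "free_y") +
    ggplot2::labs(x = "inversion genotype", y = "mean log2 expression") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
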