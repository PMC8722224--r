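#' Volcano plot of gene-level calls
#'
#' @param gene_calls Gene assignment tibble (or a `tada_result`).
#' @param fdr Threshold line (default 0.01).
#' @return A ggplot object.
#' @export
plot_volcano <- function(gene_calls, fdr = 0.01) {
  if (inherits(gene_calls, "tada_result")) {
    gene_calls <- gene_calls$gene_calls
  }
  df <- gene_calls[!is.na(gene_calls$fdr), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC,
                                   y = -log10(.data$fdr),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean logFC of assigned peak",
                  y = expression(-log[10] ~ FDR),
                  colour = paste0("FDR < ", fdr)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tada_fit <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "per-GATC logFC", y = expression(-log[10] ~ p),
                  colour = paste0("p < ", format(object$p_threshold))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tada_result <- function(object, ...) {
  plot_volcano(object)
}

#' TSS distance meta-profile plot
#'
#' @param profile Output of [tss_distance_profile()].
#' @return A ggplot object.
#' @export
plot_tss_profile <- function(profile) {
  df <- profile[is.finite(profile$lower) & is.finite(profile$upper), ]
  df$mid <- (df$lower + df$upper) / 2
  df <- df |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(frac = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$frac,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "signed distance to nearest TSS (bp)",
                  y = "fraction of sites", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Feature-category pie table plot
#'
#' @param proportions Output of [feature_proportions()].
#' @return A ggplot object.
#' @export
plot_feature_proportions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(x = "", y = .data$proportion,
                               fill = .data$feature)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "feature") +
    ggplot2::theme_void()
}

#' Gene-body meta-profile plot
#'
#' @param profile Output of [gene_body_profile()].
#' @return A ggplot object.
#' @export
plot_gene_body_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin, y = .data$mean_value,
                               colour = factor(.data$quantile))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "scaled position (5' to 3')", y = "mean track value",
                  colour = "expression\nquantile") +
    ggplot2::theme_minimal()
}
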