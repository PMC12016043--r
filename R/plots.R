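#' Density plot of empirical p-values by control status
#'
#' Mirrors the standard MPRA QC view: candidate/positive enhancers should
#' pile near p = 0 while negative controls spread toward large p.
#'
#' @param activity Scored activity tibble (needs `p_empirical`, `category`).
#' @param neg_categories Categories treated as negative controls.
#' @return A ggplot object.
#' @export
plot_pvalue_density <- function(activity,
                                neg_categories = c("negative_control",
                                                   "random_negative")) {
  df <- dplyr::mutate(
    activity,
    set = ifelse(.data$category %in% neg_categories,
                 "negative controls", "candidates & positives"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_empirical,
                                   fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~set, ncol = 2) +
    ggplot2::labs(x = "empirical p-value", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Violin plot of MAD scores by enhancer category
#'
#' @param activity Scored activity tibble (needs `mad_score`, `category`).
#' @param group_col Optional facet column (e.g. `"tissue"` or `"group"`).
#' @return A ggplot object.
#' @export
plot_mad_scores <- function(activity, group_col = NULL) {
  p <- ggplot2::ggplot(activity, ggplot2::aes(x = .data$category,
                                              y = .data$mad_score)) +
    ggplot2::geom_violin(fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "MAD score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(group_col)) {
    p <- p + ggplot2::facet_wrap(stats::as.formula(paste("~", group_col)))
  }
  p
}

#' Heatmap of a cross-group correlation matrix
#'
#' @param x An `mpra_correlation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mpra_correlation <- function(x, ...) {
  df <- as.data.frame(as.table(x$rho))
  names(df) <- c("group1", "group2", "rho")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group1, y = .data$group2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
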