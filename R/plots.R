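#' Plot an S-LDSC fit
#'
#' Standardized effect sizes with approximate 95% intervals, one point per
#' annotation, colored by role.
#'
#' @param object An `sldsc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sldsc_fit
#' @export
autoplot.sldsc_fit <- function(object, ...) {
  d <- object$coef
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$annotation, .data$tau_star),
                                  y = .data$tau_star, color = .data$role)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$tau_star - 1.96 * .data$tau_star_se,
      ymax = .data$tau_star + 1.96 * .data$tau_star_se)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(tau^"*"),
                  title = "Standardized per-SNP heritability effects") +
    ggplot2::theme_minimal()
}

#' Plot a disease x cell-type association scan
#'
#' Heatmap of -log10 p for positive tau*; significant (FDR) cells outlined,
#' Bonferroni-significant cells starred.
#'
#' @param object Association tibble from [fdr_correct()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot association_scan
#' @export
autoplot.association_scan <- function(object, ...) plot_scan(object, ...)

#' @rdname autoplot.association_scan
#' @param table Association tibble.
#' @export
plot_scan <- function(table, ...) {
  d <- dplyr::mutate(table, neglogp = -log10(pmax(.data$p, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$celltype, y = .data$trait,
                                  fill = .data$neglogp)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_tile(data = d[which(d$significant), , drop = FALSE],
                       fill = NA, color = "black", linewidth = 0.6) +
    ggplot2::geom_text(data = d[which(d$bonferroni), , drop = FALSE],
                       label = "*", nudge_y = 0.2, size = 5) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = expression(-log[10] ~ p)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Disease x cell-type heritability scan") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
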