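# ggplot2 displays for the two result types users look at most: the class
# composition of a classification run and the accumulated-RPKM shares.

#' Plot the class composition of a classification result
#'
#' Bar chart of call counts per class, split by the criterion that fired.
#'
#' @param object An `sfp_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfp_result
#' @export
autoplot.sfp_result <- function(object, ...) {
  d <- filter(object$summary, .data$n > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sfp_class, y = .data$n,
                                  fill = .data$fired_criterion)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proteins", fill = "criterion",
                  title = "SFP classification") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot expression shares
#'
#' Bar chart of accumulated-RPKM shares per group (class or functional
#' category).
#'
#' @param shares Output of [expression_share()] / [class_expression_share()].
#' @return A ggplot object.
#' @export
plot_expression_share <- function(shares) {
  ggplot2::ggplot(shares,
                  ggplot2::aes(x = stats::reorder(.data$group, -.data$share_pct),
                               y = .data$share_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "share of accumulated RPKM (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot target and decoy score distributions
#'
#' Overlaid score histograms with the FDR cutoff marked; a quick visual of
#' how separable the target and decoy populations are.
#'
#' @param psms A PSM tibble.
#' @param alpha FDR level for the cutoff line.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(psms, alpha = 0.01) {
  cut <- fdr_threshold(psms, alpha)
  ggplot2::ggplot(psms, ggplot2::aes(x = .data$score, fill = .data$is_decoy)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 60) +
    ggplot2::geom_vline(xintercept = cut$score_cutoff, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "firebrick"),
                               labels = c("target", "decoy"), name = NULL) +
    ggplot2::labs(x = "search score", y = "PSMs") +
    ggplot2::theme_minimal()
}
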