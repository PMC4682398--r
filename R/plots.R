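#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an incremental-feature-selection curve
#'
#' Mean cross-validated AUC against the number of retained mRMR-ordered
#' features, with the selected prefix marked.
#'
#' @param object A `nedd_ifs` (or `nedd_fit`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nedd_ifs <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_features, y = .data$auc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$k_star, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "Number of features",
      y = "Mean cross-validated AUC",
      title = "Incremental feature selection",
      subtitle = paste0("Selected prefix: ", object$k_star, " features")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.nedd_ifs
#' @export
autoplot.nedd_fit <- function(object, ...) autoplot.nedd_ifs(object$ifs, ...)

#' Plot a ROC curve
#'
#' @param object A `nedd_roc` from [roc_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nedd_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-position residue enrichment
#'
#' Displays -log10 adjusted p-values of the per-(position, residue)
#' chi-square tests from [position_enrichment()], signed by direction
#' (enriched in positive windows up, depleted down).
#'
#' @param enrichment Tibble from [position_enrichment()].
#' @param alpha Significance level drawn as a guide (default 0.05).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, alpha = 0.05) {
  df <- dplyr::mutate(
    enrichment,
    direction = ifelse(
      .data$pos_present / .data$pos_total >=
        .data$neg_present / .data$neg_total, 1, -1
    ),
    signed_log_p = .data$direction * -log10(pmax(.data$p_adjusted, 1e-300))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$signed_log_p)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * -log10(alpha),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(
      data = dplyr::filter(df, .data$p_adjusted < alpha),
      ggplot2::aes(label = .data$residue), vjust = -0.6, size = 3
    ) +
    ggplot2::labs(
      x = "Window position (relative to central K)",
      y = expression(signed ~ -log[10] ~ adjusted ~ p),
      title = "Positional residue enrichment"
    ) +
    ggplot2::theme_minimal()
}
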