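#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_vline
#'   geom_abline labs theme_minimal autoplot
#' @export
ggplot2::autoplot

#' Plot TSS metagene profiles
#'
#' One line per gene set, relative depth against bp offset from the TSS;
#' nucleosome-depleted (active) promoter sets dip below 1 at the centre.
#'
#' @param object a [metagene_profile()] tibble (profiles for several sets
#'   can be `bind_rows()`-ed first).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$mean_relative_depth,
                     colour = .data$gene_set)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey60") +
    geom_line() +
    labs(x = "offset from TSS (bp)", y = "relative depth",
         colour = "gene set") +
    theme_minimal()
}

#' Volcano plot of differential promoter coverage
#'
#' @param differential tibble from [select_differential()].
#' @param fdr_max,lfc_min thresholds drawn as guides (defaults match the
#'   selection defaults).
#' @return a ggplot.
#' @export
plot_volcano <- function(differential, fdr_max = 0.1, lfc_min = 1.0) {
  ggplot(differential,
         aes(x = .data$log2_fold_change, y = -log10(.data$p_value),
             colour = .data$selected)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_vline(xintercept = c(-lfc_min, lfc_min), linetype = "dashed",
               colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    labs(x = "log2 fold change (case / control)", y = "-log10 p",
         colour = "selected") +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' Empirical ROC curve of a [roc_analysis()] result with the chance
#' diagonal.
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  p <- object$probabilities
  y <- p$label == "case"
  thr <- c(Inf, sort(unique(p$probability), decreasing = TRUE), -Inf)
  pts <- tibble(
    fpr = vapply(thr, function(t) mean(p$probability[!y] >= t), 0),
    tpr = vapply(thr, function(t) mean(p$probability[y] >= t), 0))
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line(colour = "firebrick") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)", object$auc,
                         object$auc_ci_low, object$auc_ci_high)) +
    theme_minimal()
}
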