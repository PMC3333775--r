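# ggplot2 visualisations of result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_col
#'   geom_histogram labs facet_wrap theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Plot averaged ROC curves of an evaluation report
#'
#' @param object An [evaluate_scenario()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot(object$roc,
         aes(x = 1 - .data$specificity, y = .data$mean_sensitivity,
             colour = .data$method)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                colour = "grey60") +
    geom_line() +
    labs(x = "1 - specificity", y = "sensitivity", colour = "method",
         title = "Average ROC curves") +
    theme_minimal()
}

#' Plot exclusive-discovery fractions
#'
#' Bar chart of the mean EF (single data types) and EF* (integration
#' methods) of an evaluation report.
#'
#' @param report An [evaluate_scenario()] result.
#' @return A ggplot.
#' @export
plot_exclusive_fractions <- function(report) {
  ggplot(report$ef,
         aes(x = .data$method, y = .data$mean_ef, fill = .data$kind)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "mean exclusive-discovery fraction", fill = NULL) +
    theme_minimal()
}

#' Histogram of gene scores
#'
#' @param object A [score_genes()] table.
#' @param ... Unused.
#' @return A ggplot faceted by score column.
#' @export
autoplot.gene_score_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("gene", grep("^s_", names(object), value = TRUE))],
    -"gene", names_to = "score_type", values_to = "score")
  ggplot(long, aes(x = .data$score)) +
    geom_histogram(bins = 50) +
    facet_wrap(~score_type, scales = "free") +
    labs(x = "gene-to-phenotype association score", y = "genes") +
    theme_minimal()
}
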