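#' Plot PAC scores across candidate cluster numbers
#'
#' @param object a [consensus_cluster()] result.
#' @param ... unused.
#' @return a ggplot: PAC versus k, chosen k highlighted.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  df <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$pac)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "number of clusters k",
                  y = "proportion of ambiguous clustering (PAC)") +
    ggplot2::theme_minimal()
}

#' Heatmap of one consensus matrix
#'
#' @param result a [consensus_cluster()] result.
#' @param k which evaluated k to show.
#' @return a ggplot tile heatmap with samples ordered by final labels.
#' @export
plot_consensus_matrix <- function(result, k) {
  stopifnot(inherits(result, "consensus_result"))
  cm <- result$per_k[[as.character(k)]]$consensus
  ord <- order(result$per_k[[as.character(k)]]$labels)
  cm <- cm[ord, ord]
  df <- tibble::as_tibble(cm, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "consensus") |>
    dplyr::mutate(sample_a = factor(.data$sample_a, levels = rownames(cm)),
                  sample_b = factor(.data$sample_b, levels = rownames(cm)))
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_a, .data$sample_b,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "navy", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "consensus") +
    ggplot2::theme_void()
}

#' Boxplots of signature scores by sample group
#'
#' @param scores sets x samples matrix (e.g. [gsva_scores()]).
#' @param groups group labels aligned to columns.
#' @return a ggplot: score distributions per group, one facet per signature.
#' @export
plot_score_groups <- function(scores, groups) {
  df <- tidy_scores(scores)
  df$group <- groups[match(df$sample_id, colnames(scores))]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~signature) +
    ggplot2::labs(x = NULL, y = "enrichment score") +
    ggplot2::theme_minimal()
}

#' Plot classifier feature importances
#'
#' @param object a [fit_and_evaluate()] report.
#' @param top_n show at most this many features.
#' @param ... unused.
#' @return a ggplot bar chart sorted by importance.
#' @method autoplot classifier_report
#' @export
autoplot.classifier_report <- function(object, top_n = 20L, ...) {
  df <- head(object$importances, top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, .data$importance),
                                   y = .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "importance",
                  title = sprintf("%s (validation AUROC %.3f)",
                                  object$model_kind, object$validation_auroc)) +
    ggplot2::theme_minimal()
}

#' Plot the recursive-feature-elimination path
#'
#' @param object a [recursive_feature_elimination()] result.
#' @param ... unused.
#' @return a ggplot: CV AUROC versus retained feature count.
#' @method autoplot rfe_result
#' @export
autoplot.rfe_result <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$n_features, y = .data$cv_auroc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = max(object$path$cv_auroc) - 0.005,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "features retained", y = "CV AUROC") +
    ggplot2::theme_minimal()
}
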