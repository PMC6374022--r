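# ggplot2 displays for each result type.

#' Scree plot for choosing the number of topics
#'
#' @param object A `scree_table` from [scree()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scree_table
#' @export
autoplot.scree_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$component, .data$singular_value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "component", y = "singular value",
                  title = "Scree of the centered phenotype matrix") +
    ggplot2::theme_minimal()
}

#' Objective trace of an NMF fit
#'
#' @param object A `topic_model`.
#' @param ... Unused.
#' @return A ggplot of the (non-increasing) penalized objective per sweep.
#' @method autoplot topic_model
#' @export
autoplot.topic_model <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$objective_trace) - 1L,
               objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sweep", y = "penalized objective") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-topic descriptor weights
#'
#' @param desc A [top_descriptors()] table.
#' @return A ggplot, one facet per topic.
#' @export
plot_descriptors <- function(desc) {
  ggplot2::ggplot(desc,
                  ggplot2::aes(.data$weight,
                               stats::reorder(.data$phecode, .data$weight))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~topic, scales = "free_y") +
    ggplot2::labs(x = "topic-phenotype weight", y = NULL) +
    ggplot2::theme_minimal()
}

#' Topic prevalence bar chart
#'
#' @param assignments Output of [assign_topics()].
#' @return A ggplot of individuals per (argmax-assigned) topic.
#' @export
plot_topic_prevalence <- function(assignments) {
  prev <- attr(assignments, "prevalence")
  ggplot2::ggplot(prev, ggplot2::aes(.data$topic, .data$n_individuals)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "individuals assigned") +
    ggplot2::theme_minimal()
}

#' Manhattan-style PheWAS plot
#'
#' @param object A `phewas_result`.
#' @param ... Unused.
#' @return A ggplot of -log10 p per phecode with the Bonferroni line.
#' @method autoplot phewas_result
#' @export
autoplot.phewas_result <- function(object, ...) {
  df <- filter(object, .data$tested) |>
    mutate(idx = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$idx, -log10(.data$p_value))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "bonferroni")),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "phecode", y = expression(-log[10](p)),
                  title = "PheWAS") +
    ggplot2::theme_minimal()
}

#' Stability-scan summary plot
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot of agreement against the scanned regularization weight,
#'   faceted by L1 ratio and coloured by k.
#' @method autoplot stability_report
#' @export
autoplot.stability_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$lam, .data$agreement,
                               colour = factor(.data$k),
                               group = interaction(.data$k, .data$seed))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~gamma, labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = expression(lambda), y = "agreement vs base setting",
                  colour = "k") +
    ggplot2::theme_minimal()
}
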