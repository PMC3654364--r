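# broom-style verbs and plot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-iteration view of an ICCF run
#'
#' @param x An `iccf_result`.
#' @param ... Unused.
#' @return Tibble with one row per pass: `iteration`, `nodes_removed`.
#' @export
tidy.iccf_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$removed_per_iteration),
                 nodes_removed = x$removed_per_iteration)
}

#' One-row summary of an ICCF run
#'
#' @param x An `iccf_result`.
#' @param ... Unused.
#' @return One-row tibble: `iterations`, `converged`, `n_clusters`,
#'   `n_nodes`, `nodes_removed`.
#' @export
glance.iccf_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 n_clusters = nrow(x$clusters),
                 n_nodes = nrow(x$graph$nodes),
                 nodes_removed = sum(x$removed_per_iteration))
}

#' Long view of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble with `metric`, `value` rows for every scalar metric.
#' @export
tidy.evaluation_report <- function(x, ...) {
  row <- glance(x)
  tibble::tibble(metric = names(row),
                 value = as.double(unlist(row, use.names = FALSE)))
}

#' Plot score components per cluster
#'
#' Stacked view of the weighted S / I / F contributions to each cluster's
#' combined score, ordered by score.
#'
#' @param scores Tibble from [score_clusters()].
#' @param weights The weight triple the scores were combined with.
#' @return A ggplot object.
#' @export
plot_cluster_scores <- function(scores, weights = c(1, 1, 1) / 3) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(scores,
                  S = weights[1L] * .data$S,
                  I = weights[2L] * .data$I_norm,
                  F = weights[3L] * .data$F),
    cols = c("S", "I", "F"), names_to = "component",
    values_to = "contribution")
  long$component <- factor(long$component, levels = c("S", "I", "F"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(factor(.data$cluster_id),
                                                  -.data$score),
                               y = .data$contribution,
                               fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster", y = "weighted score contribution",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_cluster_scores
#' @param object,... `autoplot` arguments (`object` is an `iccf_result`).
#' @export
autoplot.iccf_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$iteration),
                                  y = .data$nodes_removed)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "ICCF pass", y = "nodes removed") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cluster_scores
#' @export
autoplot.evaluation_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
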