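#' Precision-at-k and vote accuracy over a menu of k
#'
#' Classifies the same query set at each odd `k` and tabulates
#' precision-at-k alongside majority-vote accuracy. At k = 1 the two
#' coincide exactly.
#'
#' @param index An `lsh_index` over training embeddings.
#' @param targets Labelled feature tibble of queries.
#' @param ks Odd k values. Default `c(1, 3, 5, 7)`.
#' @return Tibble with `k`, `precision_at_k`, `vote_accuracy`.
#' @export
evaluate_k_menu <- function(index, targets, ks = c(1L, 3L, 5L, 7L)) {
  purrr::map_dfr(ks, function(k) {
    res <- batch_classify(index, targets, k = k)
    tibble::tibble(k = as.integer(k),
                   precision_at_k = precision_at_k(res),
                   vote_accuracy = mean(res$predicted_entity == res$truth))
  })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the package's
#' result objects: cohort composition bars, per-run metric dots with
#' means, and the vote breakdown of a single retrieval.
#'
#' @param object A `cohort_summary`, `metric_report` or
#'   `retrieval_result`.
#' @param block For cohort summaries: which count block to show
#'   (`"entity"`, `"sex"`, `"location"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @name radrec-autoplot
NULL

#' @rdname radrec-autoplot
#' @export
autoplot.cohort_summary <- function(object, block = "entity", ...) {
  d <- object$counts[object$counts$block == block, ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$level, .data$pct),
                                  y = .data$pct)) +
    ggplot2::geom_col(fill = "#3B6FB6") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of patients",
                  title = paste("Cohort composition by", block)) +
    ggplot2::theme_minimal()
}

#' @rdname radrec-autoplot
#' @export
autoplot.metric_report <- function(object, ...) {
  ggplot2::ggplot(object$per_run,
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, position =
                          ggplot2::position_jitter(width = 0.05, height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "#B63B3B",
                          size = 3, shape = 18) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "value",
                  title = sprintf("Shuffled-run metrics (k = %d, %d runs)",
                                  object$k, object$n_runs)) +
    ggplot2::theme_minimal()
}

#' @rdname radrec-autoplot
#' @export
autoplot.retrieval_result <- function(object, ...) {
  d <- tibble::tibble(entity = names(object$vote_breakdown),
                      votes = as.integer(object$vote_breakdown))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$entity,
                                                     .data$votes),
                                  y = .data$votes)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$entity ==
                                     object$predicted_entity),
                      show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2E7D32",
                                          `FALSE` = "grey60")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "neighbour votes",
                  title = paste("Majority vote:", object$predicted_entity)) +
    ggplot2::theme_minimal()
}

#' Plot a precision-at-k curve
#'
#' @param k_menu Output of [evaluate_k_menu()].
#' @return A ggplot object.
#' @export
plot_precision_at_k <- function(k_menu) {
  d <- tidyr::pivot_longer(k_menu, -"k", names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(d$k)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "proportion", title = "Retrieval quality by k") +
    ggplot2::theme_minimal()
}
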