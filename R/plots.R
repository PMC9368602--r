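#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a NodeRank prediction
#'
#' Candidate diseases ordered by NodeRank score, with the standard-disease
#' threshold as a dashed line; predicted diseases are filled.
#'
#' @param object A `dxr_rank` from [predict.dxr_subnetwork()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dxr_rank
#' @export
autoplot.dxr_rank <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$disease_id, .data$nr),
    y = .data$nr, fill = .data$predicted)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey70"),
                               name = "predicted") +
    ggplot2::labs(x = NULL, y = "NodeRank score",
                  title = paste0("Record ", object$record_id),
                  subtitle = sprintf("threshold = %.4f (standard disease)",
                                     object$threshold)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold metrics of a cross-validated evaluation
#'
#' One panel per metric: per-fold values as points, the cross-fold mean as a
#' crossbar.
#'
#' @param object A `dxr_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dxr_cv
#' @export
autoplot.dxr_cv <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3) +
    ggplot2::scale_colour_brewer(palette = "Set2", name = "fold") +
    ggplot2::labs(x = NULL, y = "value",
                  title = sprintf("%d-fold evaluation", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the category/weight composition of a knowledge network
#'
#' Edge counts per finding category, filled by edge weight.
#'
#' @param object A [knowledge_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dxr_kn
#' @export
autoplot.dxr_kn <- function(object, ...) {
  df <- object$edges |>
    dplyr::count(.data$category, .data$weight)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = factor(.data$weight))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues", name = "edge weight") +
    ggplot2::labs(x = "finding category (per edge)", y = "edges",
                  title = sprintf("Knowledge network (%d diseases, %d findings)",
                                  nrow(object$diseases), nrow(object$findings)),
                  subtitle = paste("weight scheme", object$scheme$name)) +
    ggplot2::theme_minimal()
}
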