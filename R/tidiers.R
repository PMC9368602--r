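#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a knowledge network into its edge list
#'
#' @param x A [knowledge_network()].
#' @param ... Unused.
#' @return A tibble with one row per edge: ids, display names, category and
#'   weight.
#' @method tidy dxr_kn
#' @export
tidy.dxr_kn <- function(x, ...) {
  x$edges |>
    dplyr::left_join(x$findings, by = "finding_id") |>
    dplyr::left_join(x$diseases, by = "disease_id") |>
    dplyr::select("finding_id", "finding_name", "category",
                  "disease_id", "disease_name", "weight")
}

#' @rdname tidy.dxr_kn
#' @method glance dxr_kn
#' @export
glance.dxr_kn <- function(x, ...) {
  tibble::tibble(
    n_diseases = nrow(x$diseases),
    n_findings = nrow(x$findings),
    n_edges = nrow(x$edges),
    scheme = x$scheme$name
  )
}

#' Tidy a NodeRank prediction
#'
#' @param x A `dxr_rank` from [predict.dxr_subnetwork()].
#' @param ... Unused.
#' @return One row per candidate disease: `disease_id`, `nr`, `predicted`.
#' @method tidy dxr_rank
#' @export
tidy.dxr_rank <- function(x, ...) {
  x$scores |>
    dplyr::mutate(predicted = .data$nr >= x$threshold)
}

#' @rdname tidy.dxr_rank
#' @method glance dxr_rank
#' @export
glance.dxr_rank <- function(x, ...) {
  tibble::tibble(
    record_id = x$record_id,
    threshold = x$threshold,
    d = x$d,
    n_candidates = nrow(x$scores),
    n_predicted = length(x$predicted)
  )
}

#' Tidy a metrics report
#'
#' @param x A `dxr_metrics` from [evaluate_predictions()].
#' @param ... Unused.
#' @return `tidy()`: a long tibble (`metric`, `value`); `glance()`: one wide
#'   row including `n_records` and `q_labels`.
#' @method tidy dxr_metrics
#' @export
tidy.dxr_metrics <- function(x, ...) {
  vals <- unclass(x)[c("hamming_loss", "one_error", "ranking_loss",
                       "average_precision", "micro_precision",
                       "micro_recall", "micro_f1")]
  tibble::tibble(metric = names(vals), value = unlist(vals, use.names = FALSE))
}

#' @rdname tidy.dxr_metrics
#' @method glance dxr_metrics
#' @export
glance.dxr_metrics <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a cross-validated evaluation
#'
#' @param x A `dxr_cv` from [cross_validate()].
#' @param ... Unused.
#' @return `tidy()`: one row per fold and metric; `glance()`: one row per
#'   metric with mean and SD.
#' @method tidy dxr_cv
#' @export
tidy.dxr_cv <- function(x, ...) {
  x$per_fold |>
    tidyr::pivot_longer(-c("fold", "n_records"),
                        names_to = "metric", values_to = "value")
}

#' @rdname tidy.dxr_cv
#' @method glance dxr_cv
#' @export
glance.dxr_cv <- function(x, ...) {
  x$summary
}
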