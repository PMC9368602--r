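#' Edge-weighted NodeRank scores
#'
#' NodeRank is an edge-weighted PageRank variant: a node's rank is
#' `NR(v) = (1 - d) + d * sum over in-neighbours u of NR(u) * w(u, v) / outweight(u)`,
#' where `outweight(u)` is the total weight of `u`'s out-edges and `d` is the
#' damping factor. The `(1 - d)` term is not divided by the node count, so
#' nodes with no in-edges converge to exactly `1 - d`; dangling nodes
#' contribute nothing. Scores are computed by Jacobi iteration from a uniform
#' start of 1, stopping when the largest absolute change drops below `tol`.
#' On the bipartite patient subnetworks the iteration is exact after two
#' sweeps.
#'
#' @param edges A data frame of directed edges with columns `from`, `to`,
#'   `weight` (all weights > 0), or a [build_subnetwork()] object.
#' @param d Damping factor in `(0, 1)`; default 0.85.
#' @param tol Convergence tolerance on the max absolute change; default 1e-10.
#' @param max_iter Iteration cap; default 100.
#' @param nodes Optional character vector of node ids (isolated nodes that
#'   appear in no edge).
#' @return A tibble with columns `node`, `nr`, sorted by descending `nr`
#'   then ascending `node`.
#' @examples
#' edges <- data.frame(from = c("f1", "f2", "f2"), to = c("A", "A", "B"),
#'                     weight = 3)
#' noderank_scores(edges, d = 0.85)
#' @export
noderank_scores <- function(edges, d = 0.85, tol = 1e-10, max_iter = 100L,
                            nodes = NULL) {
  if (inherits(edges, "dxr_subnetwork")) {
    nodes <- unique(c(nodes, edges$nodes$id))
    edges <- edges$edges
  }
  if (!(is.numeric(d) && length(d) == 1L && d > 0 && d < 1)) {
    rlang::abort("damping factor d must lie strictly inside (0, 1)",
                 class = "dxr_contract_error")
  }
  if (nrow(edges) && any(!is.finite(edges$weight) | edges$weight <= 0)) {
    rlang::abort("all edge weights must be finite and > 0",
                 class = "dxr_contract_error")
  }
  ids <- sort(unique(c(edges$from, edges$to, nodes)))
  nr <- noderank_vec(edges, ids, d = d, tol = tol, max_iter = max_iter)
  tibble::tibble(node = names(nr), nr = unname(nr)) |>
    dplyr::arrange(dplyr::desc(nr), node)
}

# fixed-point iteration on integer-indexed edges; returns named vector
noderank_vec <- function(edges, ids, d, tol, max_iter) {
  n <- length(ids)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  if (nrow(edges) == 0L) return(stats::setNames(rep(1 - d, n), ids))
  from <- match(edges$from, ids)
  to <- match(edges$to, ids)
  w <- edges$weight
  outw <- numeric(n)
  ow <- tapply(w, from, sum)
  outw[as.integer(names(ow))] <- ow
  frac <- w / outw[from]                       # w(u,v) / outweight(u)
  nr <- rep(1, n)
  for (it in seq_len(max_iter)) {
    incoming <- numeric(n)
    contrib <- nr[from] * frac
    agg <- tapply(contrib, to, sum)
    incoming[as.integer(names(agg))] <- agg
    new_nr <- (1 - d) + d * incoming
    delta <- max(abs(new_nr - nr))
    nr <- new_nr
    if (delta < tol) return(stats::setNames(nr, ids))
  }
  rlang::abort(sprintf("NodeRank did not converge after %d iterations (residual %.3g)",
                       max_iter, delta),
               class = "dxr_convergence_error")
}

#' Multi-label disease prediction from a patient subnetwork
#'
#' Runs [noderank_scores()] on the subnetwork and outputs every candidate
#' disease whose NodeRank score is greater than or equal to the score of the
#' standard disease node (the calibration threshold). The reserved
#' calibration nodes are never part of the prediction. On every subnetwork
#' the threshold equals `(1 - d)(1 + d)` in closed form: the gold standard
#' node scores exactly `1 - d` and feeds its full weight into the standard
#' disease.
#'
#' @param object A [build_subnetwork()] object.
#' @param d Damping factor, default 0.85.
#' @param ... Passed on to [noderank_scores()] (`tol`, `max_iter`).
#' @return An object of class `dxr_rank`: `record_id`, a `scores` tibble
#'   (`disease_id`, `nr`; candidate diseases only), the `threshold`, and
#'   `predicted` — disease ids with `nr >= threshold`, sorted by descending
#'   score then ascending id.
#' @examples
#' kn <- knowledge_network(
#'   diseases = data.frame(disease_id = c("A", "B")),
#'   findings = data.frame(finding_id = c("f1", "f2")),
#'   edges = data.frame(finding_id = c("f1", "f2", "f2"),
#'                      disease_id = c("A", "A", "B"),
#'                      category = "common")
#' )
#' sub <- build_subnetwork("r1", c("f1", "f2"), kn)
#' predict(sub)
#' @export
predict.dxr_subnetwork <- function(object, d = 0.85, ...) {
  ranks <- noderank_scores(object, d = d, ...)
  nr <- stats::setNames(ranks$nr, ranks$node)
  threshold <- unname(nr[standard_disease_id()])
  disease_ids <- object$nodes$id[object$nodes$type == "disease"]
  scores <- ranks |>
    dplyr::filter(.data$node %in% disease_ids) |>
    dplyr::rename(disease_id = "node")
  predicted <- scores$disease_id[scores$nr >= threshold]
  structure(
    list(record_id = object$record_id, scores = scores,
         threshold = threshold, d = d, predicted = predicted),
    class = "dxr_rank"
  )
}

#' @export
print.dxr_rank <- function(x, ...) {
  cat(sprintf("<dxr_rank %s> threshold %.4f; %d of %d candidate diseases predicted\n",
              x$record_id, x$threshold, length(x$predicted), nrow(x$scores)))
  if (nrow(x$scores)) print(utils::head(tidy(x), 10))
  invisible(x)
}

#' Support ratio of a candidate disease
#'
#' The sum over a disease's supporting findings of
#' `w(f, D) / outweight(f)` within the subnetwork. Because the gold standard
#' node has ratio exactly 1 and every finding scores `1 - d`, a disease is
#' predicted if and only if its support ratio reaches 1 — a damping-free,
#' directly interpretable restatement of the threshold rule.
#'
#' @param sub A [build_subnetwork()] object.
#' @param disease_id A disease id present in the subnetwork.
#' @return A single number, `>= 0`.
#' @export
support_ratio <- function(sub, disease_id) {
  stopifnot(inherits(sub, "dxr_subnetwork"))
  if (!disease_id %in% sub$nodes$id[sub$nodes$type == "disease"]) {
    rlang::abort(paste0("disease not present in subnetwork: ", disease_id),
                 class = "dxr_contract_error")
  }
  e <- sub$edges
  outw <- tapply(e$weight, e$from, sum)
  sel <- e$to == disease_id
  sum(e$weight[sel] / outw[e$from[sel]])
}
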