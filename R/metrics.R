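#' Assemble labelled predictions for evaluation
#'
#' The evaluation functions consume a tibble with one row per record and
#' list-columns: `scores` (named numeric vectors; labels absent from a
#' record's subnetwork are taken as score 0), `predicted` (character label
#' sets) and `gold` (non-empty character label sets). `labeled_predictions()`
#' validates that shape and attaches the full label space.
#'
#' @param preds A data frame with columns `record_id`, `scores`, `predicted`,
#'   `gold` (the latter three list-columns).
#' @param labels Full label space; default: sorted union of all gold,
#'   predicted and scored labels.
#' @return The validated tibble with a `labels` attribute.
#' @export
labeled_predictions <- function(preds, labels = NULL) {
  preds <- tibble::as_tibble(preds)
  needed <- c("record_id", "scores", "predicted", "gold")
  if (!all(needed %in% names(preds))) {
    rlang::abort(paste0("predictions need columns ",
                        paste(needed, collapse = ", ")),
                 class = "dxr_contract_error")
  }
  if (nrow(preds) == 0) {
    rlang::abort("empty prediction list", class = "dxr_contract_error")
  }
  if (is.null(labels)) {
    labels <- sort(unique(c(unlist(preds$gold), unlist(preds$predicted),
                            unlist(lapply(preds$scores, names)))))
  }
  if (length(labels) < 1) {
    rlang::abort("label space must contain at least one label",
                 class = "dxr_contract_error")
  }
  if (any(lengths(preds$gold) == 0)) {
    rlang::abort("every record needs a non-empty gold label set",
                 class = "dxr_contract_error")
  }
  stray <- setdiff(unique(c(unlist(preds$gold), unlist(preds$predicted))), labels)
  if (length(stray)) {
    rlang::abort(paste0("label(s) outside the label space: ",
                        paste(utils::head(stray, 5), collapse = ", ")),
                 class = "dxr_contract_error")
  }
  attr(preds, "labels") <- labels
  preds
}

# dense score vector over the full label space (missing -> 0)
full_scores <- function(scores, labels) {
  out <- stats::setNames(rep(0, length(labels)), labels)
  if (length(scores)) {
    keep <- intersect(names(scores), labels)
    out[keep] <- scores[keep]
  }
  out
}

# deterministic total-order rank: 1 + #{strictly greater} + #{tied, smaller id}
score_ranks <- function(s) {
  ord <- order(-s, names(s))
  r <- integer(length(s))
  r[ord] <- seq_along(s)
  stats::setNames(r, names(s))
}

#' Hamming loss
#'
#' Mean over records of the size of the symmetric difference between the
#' predicted and gold label sets, divided by the label-space size `Q`.
#'
#' @inheritParams labeled_predictions
#' @return A number in `[0, 1]`.
#' @export
hamming_loss <- function(preds, labels = NULL) {
  preds <- labeled_predictions(preds, labels)
  q <- length(attr(preds, "labels"))
  mean(purrr::map2_dbl(preds$predicted, preds$gold, function(p, g) {
    (length(setdiff(p, g)) + length(setdiff(g, p))) / q
  }))
}

#' One-error
#'
#' Fraction of records whose single top-scoring label (score ties broken
#' towards the lexicographically smallest label id) is not in the gold set.
#'
#' @inheritParams labeled_predictions
#' @return A number in `[0, 1]`.
#' @export
one_error <- function(preds, labels = NULL) {
  preds <- labeled_predictions(preds, labels)
  labs <- attr(preds, "labels")
  mean(purrr::map2_dbl(preds$scores, preds$gold, function(s, g) {
    fs <- full_scores(s, labs)
    top <- names(fs)[order(-fs, names(fs))][1]
    as.numeric(!top %in% g)
  }))
}

#' Ranking loss
#'
#' Mean over records of the fraction of (gold, non-gold) label pairs that are
#' mis-ordered, counting score ties as loss: a pair counts when
#' `f(gold) <= f(non-gold)`. Records whose gold set covers the entire label
#' space have no pairs and are skipped with a warning.
#'
#' @inheritParams labeled_predictions
#' @return A number in `[0, 1]`.
#' @export
ranking_loss <- function(preds, labels = NULL) {
  preds <- labeled_predictions(preds, labels)
  labs <- attr(preds, "labels")
  per <- purrr::map2_dbl(preds$scores, preds$gold, function(s, g) {
    comp <- setdiff(labs, g)
    if (!length(comp)) return(NA_real_)
    fs <- full_scores(s, labs)
    bad <- sum(outer(fs[g], fs[comp], `<=`))
    bad / (length(g) * length(comp))
  })
  if (anyNA(per)) {
    rlang::warn(sprintf("%d record(s) with gold = full label space skipped in ranking loss",
                        sum(is.na(per))))
  }
  mean(per, na.rm = TRUE)
}

#' Average precision
#'
#' For each record, gold labels are ranked by score under a deterministic
#' total order (`rank = 1 + #strictly greater + #tied with smaller id`); the
#' record's score is the mean over its gold labels `y` of
#' `#(gold with rank <= rank(y)) / rank(y)`, i.e. precision at each gold
#' label's rank. By default the per-record mean is over the gold set
#' (`normalize = "gold"`, the standard definition); `"label_space"` divides
#' by `Q` instead.
#'
#' @inheritParams labeled_predictions
#' @param normalize `"gold"` (default) or `"label_space"`.
#' @return A number in `(0, 1]` for `"gold"` normalization.
#' @export
average_precision <- function(preds, labels = NULL,
                              normalize = c("gold", "label_space")) {
  normalize <- match.arg(normalize)
  preds <- labeled_predictions(preds, labels)
  labs <- attr(preds, "labels")
  mean(purrr::map2_dbl(preds$scores, preds$gold, function(s, g) {
    fs <- full_scores(s, labs)
    r <- score_ranks(fs)
    gr <- sort(r[g])
    prec <- vapply(gr, function(k) sum(gr <= k) / k, numeric(1))
    sum(prec) / if (normalize == "gold") length(g) else length(labs)
  }))
}

#' Micro-averaged precision, recall and F1
#'
#' True/false positives and false negatives are pooled over all labels and
#' records before forming the ratios; micro-F1 is
#' `sum(2 TP) / sum(2 TP + FP + FN)`. An all-zero denominator yields 0 with a
#' warning (the empty-prediction convention).
#'
#' @inheritParams labeled_predictions
#' @return A named list with `micro_precision`, `micro_recall`, `micro_f1`.
#' @export
micro_f1 <- function(preds, labels = NULL) {
  preds <- labeled_predictions(preds, labels)
  tallies <- purrr::map2(preds$predicted, preds$gold, function(p, g) {
    c(tp = length(intersect(p, g)),
      fp = length(setdiff(p, g)),
      fn = length(setdiff(g, p)))
  })
  tot <- Reduce(`+`, tallies)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      rlang::warn(paste0("zero denominator in ", what, "; reporting 0"))
      0
    } else num / den
  }
  list(
    micro_precision = safe_div(tot["tp"], tot["tp"] + tot["fp"], "micro precision") |> unname(),
    micro_recall = safe_div(tot["tp"], tot["tp"] + tot["fn"], "micro recall") |> unname(),
    micro_f1 = safe_div(2 * tot["tp"], 2 * tot["tp"] + tot["fp"] + tot["fn"], "micro F1") |> unname()
  )
}

#' Full evaluation report
#'
#' Computes all five multi-label metrics over a labelled prediction set.
#'
#' @inheritParams average_precision
#' @return An object of class `dxr_metrics`: a list with `hamming_loss`,
#'   `one_error`, `ranking_loss`, `average_precision`, `micro_precision`,
#'   `micro_recall`, `micro_f1`, `n_records`, `q_labels`.
#' @export
evaluate_predictions <- function(preds, labels = NULL,
                                 normalize = c("gold", "label_space")) {
  preds <- labeled_predictions(preds, labels)
  labs <- attr(preds, "labels")
  mf <- micro_f1(preds, labs)
  structure(
    c(list(
      hamming_loss = hamming_loss(preds, labs),
      one_error = one_error(preds, labs),
      ranking_loss = ranking_loss(preds, labs),
      average_precision = average_precision(preds, labs, normalize = normalize)
    ), mf,
    list(n_records = nrow(preds), q_labels = length(labs))),
    class = "dxr_metrics"
  )
}

#' @export
print.dxr_metrics <- function(x, ...) {
  cat(sprintf(paste0("<dxr_metrics> N=%d records, Q=%d labels\n",
                     "  HL %.4f | OE %.4f | RL %.4f | AP %.4f | micro-F1 %.4f ",
                     "(P %.4f, R %.4f)\n"),
              x$n_records, x$q_labels, x$hamming_loss, x$one_error,
              x$ranking_loss, x$average_precision, x$micro_f1,
              x$micro_precision, x$micro_recall))
  invisible(x)
}

#' k-fold split of record identifiers
#'
#' Shuffles the ids under `seed` and partitions them into `k` disjoint folds
#' whose sizes differ by at most one; the union covers all ids. Used by the
#' five-fold evaluation protocol.
#'
#' @param record_ids Character or integer vector of ids.
#' @param k Number of folds, `>= 2`.
#' @param seed Integer seed (shuffling is local; the global RNG state is
#'   untouched).
#' @return A list of `k` id vectors.
#' @export
kfold_split <- function(record_ids, k = 5L, seed) {
  n <- length(record_ids)
  if (k < 2L) rlang::abort("k must be >= 2", class = "dxr_contract_error")
  if (k > n) rlang::abort("k exceeds the number of records",
                          class = "dxr_contract_error")
  shuffled <- withr::with_seed(seed, sample(record_ids))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(shuffled, rep(seq_len(k), times = sizes))
}
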