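#' End-to-end multi-label prediction over a record corpus
#'
#' For each record: extract finding mentions from `text` (dictionary tagging
#' plus negation scoping) unless pre-extracted `mentions` are present; drop
#' negated mentions; match the affirmed ones into the knowledge network;
#' build the patient subnetwork with the calibration pair; rank with
#' NodeRank and emit every disease at or above the standard-disease
#' threshold.
#'
#' @param records Record tibble ([read_records()] / [generate_patients()]):
#'   `record_id` plus `text` and/or `mentions`.
#' @param kn A [knowledge_network()].
#' @param lex Lexicon for text extraction and exact matching; default
#'   [lexicon_from_kn()].
#' @param scheme Weight scheme; defaults to the KN's active scheme (the
#'   network's weights are re-derived when it differs).
#' @param d Damping factor, default 0.85.
#' @param sim_threshold Similarity-match threshold, default 0.5.
#' @param window Negation window in tokens, default 2.
#' @param similarity_fn See [match_findings()].
#' @return A tibble with one row per record: `record_id`, `threshold`,
#'   `scores` (named NR vectors over candidate diseases), `predicted`
#'   (list of disease ids), `n_matched`, `n_unmatched`.
#' @export
predict_records <- function(records, kn, lex = lexicon_from_kn(kn),
                            scheme = kn$scheme, d = 0.85,
                            sim_threshold = 0.5, window = 2L,
                            similarity_fn = string_similarity) {
  stopifnot(inherits(kn, "dxr_kn"))
  if (!identical(scheme, kn$scheme)) kn <- apply_scheme(kn, scheme)
  has_mentions <- "mentions" %in% names(records)
  has_text <- "text" %in% names(records)
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    mentions <- if (has_mentions) records$mentions[[i]] else NULL
    if (is.null(mentions)) {
      if (!has_text || is.na(records$text[i])) {
        rlang::abort(paste0("record ", records$record_id[i],
                            " has neither text nor mentions"),
                     class = "dxr_contract_error")
      }
      mentions <- extract_mentions(records$text[i], lex, window = window)
      mentions$negated <- mentions$polarity == "negated"
    }
    affirmed <- mentions[!mentions$negated, , drop = FALSE]
    if ("finding_id" %in% names(affirmed) && !anyNA(affirmed$finding_id)) {
      # pre-resolved mentions: trust the ids
      matches <- tibble::tibble(surface = affirmed$surface,
                                finding_id = affirmed$finding_id,
                                method = "exact", similarity = 1)
    } else {
      matches <- match_findings(
        tibble::tibble(surface = affirmed$surface, polarity = "affirmed"),
        kn, lex = lex, threshold = sim_threshold, similarity_fn = similarity_fn)
    }
    sub <- build_subnetwork(records$record_id[i], matches, kn, scheme = kn$scheme)
    rank <- predict(sub, d = d)
    tibble::tibble(
      record_id = records$record_id[i],
      threshold = rank$threshold,
      scores = list(stats::setNames(rank$scores$nr, rank$scores$disease_id)),
      predicted = list(rank$predicted),
      n_matched = sum(!is.na(matches$finding_id)),
      n_unmatched = sum(is.na(matches$finding_id))
    )
  })
  dplyr::bind_rows(rows)
}

#' Evaluate predictions against gold labels
#'
#' Joins a prediction tibble with the corpus gold labels and computes the
#' five multi-label metrics over the label space (by default the union of
#' gold, predicted and scored labels). When `labels` is given explicitly —
#' e.g. the corpus diseases, while the knowledge network knows many more —
#' predictions and scores are restricted to that space before scoring:
#' candidate diseases outside the evaluation space count neither for nor
#' against the model.
#'
#' @param preds Prediction tibble from [predict_records()].
#' @param records Record tibble carrying a `gold` list-column.
#' @param labels Optional full label space.
#' @return A `dxr_metrics` report (see [evaluate_predictions()]).
#' @export
evaluate_corpus <- function(preds, records, labels = NULL) {
  if (!"gold" %in% names(records) || any(purrr::map_lgl(records$gold, is.null))) {
    missing <- records$record_id[purrr::map_lgl(records$gold %||% vector("list", nrow(records)), is.null)]
    rlang::abort(paste0("record(s) lacking gold labels: ",
                        paste(utils::head(missing, 5), collapse = ", ")),
                 class = "dxr_contract_error")
  }
  joined <- dplyr::inner_join(preds,
                              records[, c("record_id", "gold")],
                              by = "record_id")
  if (!is.null(labels)) {
    joined$predicted <- purrr::map(joined$predicted, intersect, labels)
    joined$scores <- purrr::map(joined$scores,
                                function(s) s[names(s) %in% labels])
  }
  evaluate_predictions(joined, labels = labels)
}

#' k-fold cross-validated evaluation
#'
#' Partitions the records into `k` folds ([kfold_split()]), runs the full
#' prediction pipeline on each test fold and reports per-fold metrics with
#' their mean and standard deviation. The knowledge network is fixed
#' evidence, not fitted, so the folds only partition the evaluation — no
#' training happens between folds.
#'
#' @inheritParams predict_records
#' @param k Number of folds, default 5.
#' @param seed Integer seed for the fold shuffle.
#' @param labels Label space passed to the metrics; default: union of gold
#'   labels across the whole corpus (shared by all folds).
#' @param ... Passed to [predict_records()].
#' @return An object of class `dxr_cv`: per-fold metric tibble plus
#'   mean/SD summary.
#' @export
cross_validate <- function(records, kn, k = 5L, seed, labels = NULL, ...) {
  folds <- kfold_split(records$record_id, k = k, seed = seed)
  if (is.null(labels)) labels <- sort(unique(unlist(records$gold)))
  metric_names <- c("hamming_loss", "one_error", "ranking_loss",
                    "average_precision", "micro_precision", "micro_recall",
                    "micro_f1")
  fold_rows <- purrr::imap(folds, function(ids, fold_i) {
    test <- records[records$record_id %in% ids, , drop = FALSE]
    preds <- predict_records(test, kn, ...)
    rep <- evaluate_corpus(preds, test, labels = labels)
    tibble::as_tibble(c(list(fold = as.integer(fold_i)), unclass(rep)[metric_names],
                        list(n_records = rep$n_records)))
  })
  per_fold <- dplyr::bind_rows(fold_rows)
  summary <- per_fold |>
    tidyr::pivot_longer(dplyr::all_of(metric_names),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(metric = factor(.data$metric, levels = metric_names)) |>
    dplyr::arrange(.data$metric) |>
    dplyr::mutate(metric = as.character(.data$metric))
  structure(list(per_fold = per_fold, summary = summary, k = k,
                 q_labels = length(labels)),
            class = "dxr_cv")
}

#' @export
print.dxr_cv <- function(x, ...) {
  cat(sprintf("<dxr_cv> %d-fold evaluation over Q=%d labels (mean ± SD)\n",
              x$k, x$q_labels))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-18s %.4f ± %.6f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Serialize a metrics report (single-shot or cross-validated) to JSON
#'
#' @param x A `dxr_metrics` or `dxr_cv` object.
#' @param path Output JSON path.
#' @param meta Optional named list embedded under `"meta"` (e.g. config and
#'   package version).
#' @export
write_metrics <- function(x, path, meta = NULL) {
  payload <- if (inherits(x, "dxr_cv")) {
    list(per_fold = x$per_fold, summary = x$summary, k = x$k,
         q_labels = x$q_labels)
  } else {
    unclass(x)
  }
  payload$meta <- c(list(package = "dxrank",
                         version = as.character(utils::packageVersion("dxrank"))),
                    meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
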