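#' Read and write patient records as JSONL
#'
#' One JSON object per line with `id`, and either `text` (raw record text)
#' or `mentions` (pre-extracted, a list of `{"surface": ..., "negated":
#' ...}`, optionally with `finding_id`); optional `gold_labels` (disease
#' ids). Pre-extracted mentions bypass the tagger downstream.
#'
#' @param path JSONL file path.
#' @return A tibble with columns `record_id`, `text` (may be `NA`),
#'   `mentions` (list-column of tibbles or `NULL`), `gold` (list-column,
#'   `NULL` when absent).
#' @export
read_records <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::map(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
  if (!length(recs)) {
    return(tibble::tibble(record_id = character(), text = character(),
                          mentions = list(), gold = list()))
  }
  tibble::tibble(
    record_id = purrr::map_chr(recs, function(r) as.character(r$id)),
    text = purrr::map_chr(recs, function(r) r$text %||% NA_character_),
    mentions = purrr::map(recs, function(r) {
      if (is.null(r$mentions)) return(NULL)
      m <- tibble::as_tibble(r$mentions)
      if (!"negated" %in% names(m)) m$negated <- FALSE
      m
    }),
    gold = purrr::map(recs, function(r) {
      g <- r$gold_labels
      if (is.null(g)) NULL else as.character(g)
    })
  )
}

#' @rdname read_records
#' @param records A record tibble (as from [generate_patients()] or
#'   [read_records()]).
#' @export
write_records <- function(records, path) {
  lines <- purrr::pmap_chr(
    list(records$record_id,
         if ("text" %in% names(records)) records$text else rep(NA_character_, nrow(records)),
         if ("mentions" %in% names(records)) records$mentions else vector("list", nrow(records)),
         if ("gold" %in% names(records)) records$gold else vector("list", nrow(records))),
    function(id, text, mentions, gold) {
      obj <- list(id = id)
      if (!is.na(text)) obj$text <- text
      if (!is.null(mentions)) {
        obj$mentions <- purrr::map(seq_len(nrow(mentions)), function(i) {
          m <- list(surface = mentions$surface[i],
                    negated = isTRUE(mentions$negated[i]))
          if ("finding_id" %in% names(mentions)) m$finding_id <- mentions$finding_id[i]
          m
        })
      }
      if (!is.null(gold)) obj$gold_labels <- gold
      jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
    })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write per-record predictions as JSONL
#'
#' One object per record: `{"id", "threshold", "scores": {disease: NR},
#' "predicted": [...]}`. Diseases absent from a record's subnetwork are
#' omitted from `scores`; downstream metrics assign them score 0.
#'
#' @param preds Prediction tibble from [predict_records()].
#' @param path Output path.
#' @export
write_predictions <- function(preds, path) {
  lines <- purrr::pmap_chr(
    list(preds$record_id, preds$threshold, preds$scores, preds$predicted),
    function(id, thr, scores, predicted) {
      jsonlite::toJSON(
        list(id = id, threshold = thr,
             scores = as.list(scores),
             predicted = as.list(predicted)),
        auto_unbox = TRUE, digits = NA)
    })
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::map(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  tibble::tibble(
    record_id = purrr::map_chr(recs, "id"),
    threshold = purrr::map_dbl(recs, "threshold"),
    scores = purrr::map(recs, function(r) unlist(r$scores) %||%
                          stats::setNames(numeric(0), character(0))),
    predicted = purrr::map(recs, function(r) as.character(unlist(r$predicted)))
  )
}
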