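#' Finding lexicon and negation cues
#'
#' The lexicon maps surface terms, as they appear in record text, to finding
#' identifiers in a companion knowledge network; negation cues are surface
#' terms (e.g. 无, "no", "denies") whose presence in a mention's left
#' context or span flips the mention's polarity to negated.
#'
#' @param entries A data frame with columns `surface`, `finding_id`.
#' @param negation_cues Character vector of cue terms.
#' @return An object of class `dxr_lexicon`.
#' @examples
#' lex <- lexicon(data.frame(surface = "abdominal pain", finding_id = "F1"))
#' @export
lexicon <- function(entries, negation_cues = default_negation_cues()) {
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("surface", "finding_id") %in% names(entries)))
  entries <- dplyr::distinct(entries[, c("surface", "finding_id")])
  if (any(!nzchar(entries$surface)) || any(!nzchar(negation_cues))) {
    rlang::abort("lexicon surfaces and negation cues must be non-empty strings",
                 class = "dxr_validation_error")
  }
  structure(list(entries = entries, negation_cues = negation_cues,
                 index = build_term_index(entries$surface)),
            class = "dxr_lexicon")
}

#' @export
print.dxr_lexicon <- function(x, ...) {
  cat(sprintf("<dxr_lexicon> %d entries, %d negation cues\n",
              nrow(x$entries), length(x$negation_cues)))
  invisible(x)
}

#' @rdname lexicon
#' @details `default_negation_cues()` ships a small demonstration list of
#'   Chinese and English cues. It is a starting point only: real clinical
#'   deployments should supply their own curated cue list via the
#'   `negation_cues` argument or [read_negation_cues()].
#' @export
default_negation_cues <- function() {
  c("无", "未", "否认", "没有", "不",
    "未见", "排除",
    "no", "not", "denies", "without", "negative")
}

#' @rdname lexicon
#' @param kn A [knowledge_network()]; every finding name becomes a surface.
#' @export
lexicon_from_kn <- function(kn, negation_cues = default_negation_cues()) {
  stopifnot(inherits(kn, "dxr_kn"))
  lexicon(tibble::tibble(surface = kn$findings$finding_name,
                         finding_id = kn$findings$finding_id),
          negation_cues = negation_cues)
}

#' Read lexicon files
#'
#' The lexicon TSV has header `surface finding_id`; the negation lexicon is
#' plain text, one cue per line.
#'
#' @param path File path.
#' @param negation_cues Cues to attach to the lexicon.
#' @param kn Optional [knowledge_network()]; if given, entries whose
#'   `finding_id` does not resolve in it raise a validation error.
#' @return [read_lexicon()] returns a `dxr_lexicon`; [read_negation_cues()] a
#'   character vector.
#' @export
read_lexicon <- function(path, negation_cues = default_negation_cues(), kn = NULL) {
  entries <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
  lex <- lexicon(entries, negation_cues = negation_cues)
  if (!is.null(kn)) {
    unresolved <- setdiff(lex$entries$finding_id, kn$findings$finding_id)
    if (length(unresolved)) {
      rlang::abort(paste0("lexicon finding_id(s) absent from the KN: ",
                          paste(utils::head(unresolved, 5), collapse = ", ")),
                   class = "dxr_validation_error")
    }
  }
  lex
}

#' @rdname read_lexicon
#' @export
read_negation_cues <- function(path) {
  cues <- readr::read_lines(path, progress = FALSE)
  cues <- cues[nzchar(trimws(cues))]
  trimws(cues)
}

#' @rdname read_lexicon
#' @param lex A `dxr_lexicon`.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "dxr_lexicon"))
  readr::write_tsv(lex$entries, path, progress = FALSE)
  invisible(path)
}
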