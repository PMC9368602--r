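#' Tokenize record text
#'
#' Clinical Chinese is tokenized at character granularity (annotation of such
#' corpora counts characters); Latin-script text at whitespace boundaries.
#' `"auto"` picks character mode when the text contains any CJK ideograph.
#'
#' @param text A single string.
#' @param method `"auto"`, `"character"` (CJK: one token per non-space
#'   character) or `"whitespace"`.
#' @return Character vector of tokens.
#' @examples
#' tokenize("患者腹痛")
#' tokenize("no abdominal pain")
#' @export
tokenize <- function(text, method = c("auto", "character", "whitespace")) {
  stopifnot(is.character(text), length(text) == 1L)
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (grepl("\\p{Han}", text, perl = TRUE)) "character" else "whitespace"
  }
  if (method == "character") {
    toks <- strsplit(gsub("\\s+", "", text), "", fixed = FALSE)[[1]]
  } else {
    toks <- strsplit(trimws(text), "\\s+")[[1]]
  }
  toks[nzchar(toks)]
}

# tokenize a lexicon surface with the tokenizer matching its script
tokenize_surface <- function(surface) tokenize(surface, method = "auto")

# precomputed matching index over a term list: token sequences sorted
# longest-first and grouped by first token (computed once per lexicon)
build_term_index <- function(surfaces) {
  term_tokens <- lapply(unique(surfaces), tokenize_surface)
  lens <- lengths(term_tokens)
  term_tokens <- term_tokens[lens > 0]
  lens <- lens[lens > 0]
  ord <- order(lens, decreasing = TRUE)
  term_tokens <- term_tokens[ord]
  lens <- lens[ord]
  first_tok <- vapply(term_tokens, `[`, character(1), 1L)
  list(term_tokens = term_tokens, lens = lens,
       by_first = split(seq_along(term_tokens), first_tok))
}

# join a token slice back into a surface string: CJK single-character tokens
# concatenate without separators, word tokens with spaces
join_tokens <- function(tokens) {
  if (length(tokens) == 0) return("")
  cjk <- all(nchar(tokens) == 1L & grepl("\\p{Han}", tokens, perl = TRUE))
  paste(tokens, collapse = if (cjk) "" else " ")
}

#' Dictionary BIO tagging by greedy forward maximum matching
#'
#' Scans the token sequence left to right; at each position the longest
#' lexicon term whose token sequence matches verbatim is tagged `B I ...` and
#' the scan resumes after it, so tagged spans never overlap. Tokens covered by
#' no term are tagged `O`. This is the default tagger; a trained sequence
#' model can replace it by supplying score matrices to [crf_decode()].
#'
#' @param tokens Character vector of tokens (see [tokenize()]).
#' @param lex A [lexicon()].
#' @return Character vector of `"B"`/`"I"`/`"O"` tags, one per token.
#' @examples
#' lex <- lexicon(data.frame(surface = "腹痛", finding_id = "F1"))
#' dictionary_tag(tokenize("患者腹痛"), lex)
#' @export
dictionary_tag <- function(tokens, lex) {
  stopifnot(inherits(lex, "dxr_lexicon"))
  if (nrow(lex$entries) == 0) {
    rlang::abort("lexicon has no entries", class = "dxr_contract_error")
  }
  n <- length(tokens)
  tags <- rep("O", n)
  idx <- lex$index %||% build_term_index(lex$entries$surface)
  term_tokens <- idx$term_tokens
  lens <- idx$lens
  by_first <- idx$by_first
  i <- 1L
  while (i <= n) {
    matched <- 0L
    cand <- by_first[[tokens[i]]]
    for (t in cand) {                      # still longest-first within token
      L <- lens[t]
      if (i + L - 1L <= n && all(tokens[i:(i + L - 1L)] == term_tokens[[t]])) {
        matched <- L
        break
      }
    }
    if (matched > 0L) {
      tags[i] <- "B"
      if (matched > 1L) tags[(i + 1L):(i + matched - 1L)] <- "I"
      i <- i + matched
    } else {
      i <- i + 1L
    }
  }
  tags
}

#' Recover finding mentions from a BIO tag sequence
#'
#' Maximal `B I ...` runs become affirmed mentions with 0-based half-open
#' token spans. A dangling `I` (following `O` or at the sequence start, as
#' imperfect external taggers sometimes emit) is repaired by treating it as
#' `B`, with a warning.
#'
#' @param tokens Character vector of tokens.
#' @param tags Aligned `"B"`/`"I"`/`"O"` tags.
#' @return A tibble with columns `start`, `end` (0-based half-open token
#'   offsets), `surface` and `polarity` (all `"affirmed"`).
#' @export
tags_to_mentions <- function(tokens, tags) {
  if (length(tokens) != length(tags)) {
    rlang::abort("tokens and tags must be aligned 1:1", class = "dxr_contract_error")
  }
  n <- length(tags)
  dangling <- which(tags == "I" & c("O", utils::head(tags, -1)) == "O")
  if (length(dangling)) {
    rlang::warn(paste0("repaired dangling I tag(s) at position(s) ",
                       paste(dangling, collapse = ", "), " by treating as B"))
    tags[dangling] <- "B"
  }
  starts <- which(tags == "B")
  if (!length(starts)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          surface = character(), polarity = character()))
  }
  ends <- vapply(starts, function(s) {
    e <- s
    while (e < n && tags[e + 1L] == "I") e <- e + 1L
    e
  }, integer(1))
  tibble::tibble(
    start = starts - 1L,
    end = ends,
    surface = vapply(seq_along(starts),
                     function(i) join_tokens(tokens[starts[i]:ends[i]]),
                     character(1)),
    polarity = "affirmed"
  )
}

# locate all (possibly overlapping) occurrences of cue token sequences;
# returns 0-based half-open spans
find_cue_spans <- function(tokens, cues) {
  n <- length(tokens)
  out <- list()
  for (cue in cues) {
    ct <- tokenize_surface(cue)
    L <- length(ct)
    if (L == 0L || L > n) next
    for (i in seq_len(n - L + 1L)) {
      if (all(tokens[i:(i + L - 1L)] == ct)) {
        out[[length(out) + 1L]] <- c(i - 1L, i - 1L + L)
      }
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 2))
  do.call(rbind, out)
}

#' Negation scoping over extracted mentions
#'
#' A mention's polarity becomes `"negated"` when a negation cue ends within
#' `window` tokens before the mention's start (a gap of `0..window` tokens),
#' or when a cue lies inside the mention span. All other mentions stay
#' affirmed. Span, order and count are never changed, and the operation is
#' idempotent.
#'
#' @param tokens Character vector of tokens.
#' @param mentions Mention tibble from [tags_to_mentions()], sorted by `start`.
#' @param cues Character vector of negation cues (default
#'   [default_negation_cues()]).
#' @param window Non-negative integer left-context width in tokens; default 2.
#' @return The mention tibble with updated `polarity`.
#' @examples
#' toks <- tokenize("无腹痛")
#' m <- tibble::tibble(start = 1L, end = 3L, surface = "腹痛", polarity = "affirmed")
#' apply_negation(toks, m, cues = "无")
#' @export
apply_negation <- function(tokens, mentions, cues = default_negation_cues(),
                           window = 2L) {
  stopifnot(window >= 0)
  if (nrow(mentions) == 0) return(mentions)
  spans <- find_cue_spans(tokens, cues)
  if (!nrow(spans)) {
    mentions$polarity <- "affirmed"
    return(mentions)
  }
  mentions$polarity <- vapply(seq_len(nrow(mentions)), function(i) {
    s <- mentions$start[i]; e <- mentions$end[i]
    gap <- s - spans[, 2]                         # tokens between cue end and span start
    before <- any(gap >= 0 & gap <= window)
    inside <- any(spans[, 1] >= s & spans[, 2] <= e)
    if (before || inside) "negated" else "affirmed"
  }, character(1))
  mentions
}

#' Extract polarity-annotated finding mentions from record text
#'
#' Convenience wrapper: [tokenize()] then [dictionary_tag()],
#' [tags_to_mentions()] and [apply_negation()].
#'
#' @inheritParams dictionary_tag
#' @inheritParams apply_negation
#' @param text A single string of record text.
#' @param method Tokenization method, see [tokenize()].
#' @return Mention tibble with columns `start`, `end`, `surface`, `polarity`.
#' @export
extract_mentions <- function(text, lex, window = 2L, method = "auto") {
  tokens <- tokenize(text, method = method)
  if (!length(tokens)) {
    return(tibble::tibble(start = integer(), end = integer(),
                          surface = character(), polarity = character()))
  }
  tags <- dictionary_tag(tokens, lex)
  mentions <- tags_to_mentions(tokens, tags)
  apply_negation(tokens, mentions, cues = lex$negation_cues, window = window)
}
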