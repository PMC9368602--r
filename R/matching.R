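# reserved calibration node ids, namespaced to avoid KN collisions
.reserved_ids <- c("__STANDARD_DISEASE__", "__GOLD_STANDARD__")

#' Reserved calibration node identifiers
#'
#' Every patient subnetwork contains a "gold standard" source node wired to a
#' "standard disease" node; the standard disease's NodeRank score is the
#' inclusion threshold for predictions. These functions return the namespaced
#' identifiers of that pair.
#' @return A single string.
#' @export
standard_disease_id <- function() .reserved_ids[1]

#' @rdname standard_disease_id
#' @export
gold_standard_id <- function() .reserved_ids[2]

char_bigrams <- function(x) {
  chars <- strsplit(x, "")[[1]]
  if (length(chars) < 2L) return(unique(chars))   # single character: unigram set
  unique(paste0(chars[-length(chars)], chars[-1]))
}

#' Character-bigram Dice similarity
#'
#' The default lexical similarity used when a mention has no exact match in
#' the knowledge network: `2 |A ∩ B| / (|A| + |B|)` over the sets of
#' character bigrams of the two strings (character sets for single-character
#' strings). Symmetric, 1 for identical strings. Purely lexical — users with
#' a semantic dictionary can pass their own function wherever a
#' `similarity_fn` argument is accepted.
#'
#' @param a,b Non-empty strings.
#' @return Similarity in `[0, 1]`.
#' @examples
#' string_similarity("腹痛", "腹痛")
#' string_similarity("abdominal pain", "abdominal mass")
#' @export
string_similarity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    rlang::abort("string_similarity requires non-empty strings",
                 class = "dxr_contract_error")
  }
  ba <- char_bigrams(a); bb <- char_bigrams(b)
  2 * length(intersect(ba, bb)) / (length(ba) + length(bb))
}

#' Match affirmed mentions against knowledge-network findings
#'
#' Exact surface match (against finding names, and lexicon surfaces if a
#' lexicon is given) wins outright. Otherwise the finding with the highest
#' `similarity_fn` score at or above `threshold` is chosen — "high similarity
#' coefficient first" — with ties broken by shorter finding name then
#' lexicographic id. Below-threshold mentions are reported as unmatched.
#'
#' @param mentions Mention tibble (columns `surface`, `polarity`); all rows
#'   must be affirmed — negated findings carry no diagnostic evidence and the
#'   caller removes them first (see [apply_negation()]).
#' @param kn A [knowledge_network()].
#' @param lex Optional [lexicon()] providing additional exact surfaces.
#' @param threshold Minimum similarity for a fuzzy match, default 0.5.
#' @param similarity_fn Function `(a, b) -> [0,1]`; default
#'   [string_similarity()].
#' @return A tibble with one row per mention: `surface`, `finding_id`
#'   (`NA` if unmatched), `method` (`"exact"`, `"similarity"`,
#'   `"unmatched"`) and `similarity`.
#' @export
match_findings <- function(mentions, kn, lex = NULL, threshold = 0.5,
                           similarity_fn = string_similarity) {
  stopifnot(inherits(kn, "dxr_kn"))
  if ("polarity" %in% names(mentions) && any(mentions$polarity != "affirmed")) {
    rlang::abort("match_findings expects affirmed mentions only; drop negated mentions first",
                 class = "dxr_contract_error")
  }
  exact <- stats::setNames(kn$findings$finding_id, kn$findings$finding_name)
  if (!is.null(lex)) {
    exact <- c(exact, stats::setNames(lex$entries$finding_id, lex$entries$surface))
  }
  n_cand <- nrow(kn$findings)
  match_one <- function(surface) {
    hit <- exact[surface]
    if (!is.na(hit)) {
      return(list(finding_id = unname(hit), method = "exact", similarity = 1))
    }
    if (n_cand == 0L) {
      return(list(finding_id = NA_character_, method = "unmatched", similarity = NA_real_))
    }
    sims <- vapply(kn$findings$finding_name, similarity_fn, numeric(1), a = surface)
    best <- max(sims)
    if (best < threshold) {
      return(list(finding_id = NA_character_, method = "unmatched", similarity = NA_real_))
    }
    cand <- which(sims == best)
    cand <- cand[order(nchar(kn$findings$finding_name[cand]),
                       kn$findings$finding_id[cand])]
    list(finding_id = kn$findings$finding_id[cand[1]],
         method = "similarity", similarity = best)
  }
  res <- purrr::map(mentions$surface, match_one)
  tibble::tibble(
    surface = mentions$surface,
    finding_id = purrr::map_chr(res, "finding_id"),
    method = purrr::map_chr(res, "method"),
    similarity = purrr::map_dbl(res, "similarity")
  )
}

#' Build the per-patient binary-weighted subnetwork
#'
#' The subnetwork contains every matched finding, every KN disease adjacent
#' to at least one matched finding, all connecting finding→disease edges with
#' their KN weights, and the calibration pair: one edge from the gold
#' standard node to the standard disease node, weighted like an auxiliary
#' examination result under `scheme`. Repeated matches of the same finding
#' collapse to one node.
#'
#' @param record_id Identifier carried through to the prediction.
#' @param matches Match tibble from [match_findings()] (unmatched rows are
#'   ignored), or a character vector of finding ids.
#' @param kn A [knowledge_network()].
#' @param scheme Weight scheme for the gold edge; defaults to the KN's.
#' @return An object of class `dxr_subnetwork`: `record_id`, a `nodes`
#'   tibble (`id`, `type` in finding/disease/reserved) and a directed
#'   `edges` tibble (`from`, `to`, `weight`).
#' @export
build_subnetwork <- function(record_id, matches, kn, scheme = kn$scheme) {
  stopifnot(inherits(kn, "dxr_kn"))
  if (is.character(matches)) {
    finding_ids <- unique(matches)
  } else {
    finding_ids <- unique(matches$finding_id[!is.na(matches$finding_id)])
  }
  unknown <- setdiff(finding_ids, kn$findings$finding_id)
  if (length(unknown)) {
    rlang::abort(paste0("matched finding id(s) absent from KN: ",
                        paste(utils::head(unknown, 5), collapse = ", ")),
                 class = "dxr_validation_error")
  }
  sub_edges <- kn$edges[kn$edges$finding_id %in% finding_ids, , drop = FALSE]
  diseases <- sort(unique(sub_edges$disease_id))
  edges <- tibble::tibble(
    from = c(sub_edges$finding_id, gold_standard_id()),
    to = c(sub_edges$disease_id, standard_disease_id()),
    weight = c(sub_edges$weight, scheme$auxiliary)
  )
  nodes <- tibble::tibble(
    id = c(sort(finding_ids), diseases, gold_standard_id(), standard_disease_id()),
    type = c(rep("finding", length(finding_ids)),
             rep("disease", length(diseases)),
             rep("reserved", 2L))
  )
  structure(list(record_id = record_id, nodes = nodes, edges = edges),
            class = "dxr_subnetwork")
}

#' @export
print.dxr_subnetwork <- function(x, ...) {
  cat(sprintf("<dxr_subnetwork %s> %d findings, %d candidate diseases, %d edges\n",
              x$record_id,
              sum(x$nodes$type == "finding"),
              sum(x$nodes$type == "disease"),
              nrow(x$edges)))
  invisible(x)
}

#' Dump a subnetwork as inspectable JSON
#'
#' The model is deliberately not a black box: the per-patient evidence graph
#' can be written out as JSON (node lists plus `(src, dst, weight)` edge
#' triples) for inspection.
#'
#' @param sub A `dxr_subnetwork`.
#' @param path Output JSON path.
#' @export
write_subnetwork <- function(sub, path) {
  stopifnot(inherits(sub, "dxr_subnetwork"))
  jsonlite::write_json(
    list(record_id = sub$record_id,
         nodes = sub$nodes,
         edges = sub$edges),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
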