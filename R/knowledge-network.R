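#' Binary-weighted disease knowledge network
#'
#' The knowledge network (KN) is a strictly bipartite weighted graph linking
#' diagnostic findings (clinical manifestations and auxiliary examination
#' results) to the diseases they support. Each edge carries the category of
#' the finding *for that disease* — the same sign can be a common
#' manifestation of one disease and only an occasional one of another — and a
#' positive weight, by default determined from the category by a
#' [weight_scheme()].
#'
#' @param diseases A data frame with columns `disease_id`, `disease_name`
#'   (name defaults to the id).
#' @param findings A data frame with columns `finding_id`, `finding_name`.
#' @param edges A data frame with columns `finding_id`, `disease_id`,
#'   `category` (one of [finding_categories()]) and optionally `weight`
#'   (`NA` entries are filled from `scheme`) and `explicit` (logical; marks
#'   weights that should survive [apply_scheme()]).
#' @param scheme A [weight_scheme()]; default `<137>`.
#' @return An object of class `dxr_kn`: a list with tibbles `diseases`,
#'   `findings`, `edges` and the active `scheme`.
#' @examples
#' kn <- knowledge_network(
#'   diseases = data.frame(disease_id = c("D1", "D2")),
#'   findings = data.frame(finding_id = c("F1", "F2")),
#'   edges = data.frame(finding_id = c("F1", "F2", "F2"),
#'                      disease_id = c("D1", "D1", "D2"),
#'                      category = c("common", "auxiliary", "occasional"))
#' )
#' kn
#' @seealso [read_kn()], [write_kn()], [apply_scheme()]
#' @export
knowledge_network <- function(diseases = NULL, findings = NULL, edges = NULL,
                              scheme = scheme_from_label("<137>")) {
  stopifnot(inherits(scheme, "dxr_weight_scheme"))
  diseases <- tibble::as_tibble(diseases %||% tibble::tibble(disease_id = character()))
  findings <- tibble::as_tibble(findings %||% tibble::tibble(finding_id = character()))
  edges    <- tibble::as_tibble(edges    %||% tibble::tibble(
    finding_id = character(), disease_id = character(), category = character()))

  if (!"disease_name" %in% names(diseases)) diseases$disease_name <- diseases$disease_id
  if (!"finding_name" %in% names(findings)) findings$finding_name <- findings$finding_id
  diseases <- dplyr::distinct(diseases[, c("disease_id", "disease_name")])
  findings <- dplyr::distinct(findings[, c("finding_id", "finding_name")])

  if (!"weight" %in% names(edges)) edges$weight <- NA_real_
  if (!"explicit" %in% names(edges)) edges$explicit <- !is.na(edges$weight)
  edges$weight <- as.numeric(edges$weight)
  fill <- is.na(edges$weight)
  edges$weight[fill] <- scheme_weight(scheme, edges$category[fill])
  edges <- edges[, c("finding_id", "disease_id", "category", "weight", "explicit")]

  kn <- structure(
    list(diseases = diseases, findings = findings,
         edges = tibble::as_tibble(edges), scheme = scheme),
    class = "dxr_kn"
  )
  validate_kn(kn)
}

#' @rdname knowledge_network
#' @param kn A `dxr_kn` object.
#' @export
validate_kn <- function(kn) {
  ed <- kn$edges
  bad_cat <- setdiff(unique(ed$category), finding_categories())
  if (length(bad_cat)) {
    rlang::abort(paste0("unknown finding category token(s): ",
                        paste(bad_cat, collapse = ", ")),
                 class = "dxr_validation_error")
  }
  if (anyDuplicated(kn$diseases$disease_id) || anyDuplicated(kn$findings$finding_id)) {
    rlang::abort("duplicate node identifiers", class = "dxr_validation_error")
  }
  both <- intersect(kn$diseases$disease_id, kn$findings$finding_id)
  if (length(both)) {
    rlang::abort(paste0("identifier(s) used as both disease and finding ",
                        "(network must be bipartite): ",
                        paste(utils::head(both, 5), collapse = ", ")),
                 class = "dxr_validation_error")
  }
  if (nrow(ed)) {
    if (any(!is.finite(ed$weight)) || any(ed$weight <= 0)) {
      rlang::abort("edge weights must be finite and > 0",
                   class = "dxr_validation_error")
    }
    if (anyDuplicated(ed[, c("finding_id", "disease_id")])) {
      rlang::abort("duplicate finding-disease edges", class = "dxr_validation_error")
    }
    missing_f <- setdiff(ed$finding_id, kn$findings$finding_id)
    missing_d <- setdiff(ed$disease_id, kn$diseases$disease_id)
    # an edge whose "finding" endpoint is actually a disease (or vice versa)
    # is a bipartiteness violation, not just a dangling reference
    if (length(intersect(missing_f, kn$diseases$disease_id)) ||
        length(intersect(missing_d, kn$findings$finding_id))) {
      rlang::abort("edge connects two nodes of the same kind (non-bipartite)",
                   class = "dxr_validation_error")
    }
    if (length(missing_f) || length(missing_d)) {
      rlang::abort(paste0("edge endpoint(s) absent from node sets: ",
                          paste(utils::head(c(missing_f, missing_d), 5),
                                collapse = ", ")),
                   class = "dxr_validation_error")
    }
  }
  if (any(c(kn$diseases$disease_id, kn$findings$finding_id) %in% .reserved_ids)) {
    rlang::abort(paste0("node ids ", paste(.reserved_ids, collapse = " / "),
                        " are reserved"), class = "dxr_validation_error")
  }
  kn
}

#' Re-derive edge weights from categories under a new scheme
#'
#' Recomputes every non-explicit edge weight from its category. Edges loaded
#' or constructed with an explicit per-edge weight keep it.
#'
#' @inheritParams validate_kn
#' @param scheme A [weight_scheme()].
#' @return The knowledge network with updated weights and active scheme.
#' @export
apply_scheme <- function(kn, scheme) {
  stopifnot(inherits(kn, "dxr_kn"), inherits(scheme, "dxr_weight_scheme"))
  derived <- !kn$edges$explicit
  kn$edges$weight[derived] <- scheme_weight(scheme, kn$edges$category[derived])
  kn$scheme <- scheme
  validate_kn(kn)
}

#' @export
print.dxr_kn <- function(x, ...) {
  cat(sprintf("<dxr_kn> %d diseases, %d findings, %d edges; scheme %s\n",
              nrow(x$diseases), nrow(x$findings), nrow(x$edges), x$scheme$name))
  if (nrow(x$edges)) {
    print(utils::head(tidy(x), 5))
    if (nrow(x$edges) > 5) cat("# ... with", nrow(x$edges) - 5, "more edges\n")
  }
  invisible(x)
}

.kn_header <- c("finding_id", "finding_name", "category",
                "disease_id", "disease_name", "weight")

#' Read / write a knowledge network in the KN TSV dialect
#'
#' One edge per row, UTF-8, header
#' `finding_id finding_name category disease_id disease_name weight`.
#' `category` is one of [finding_categories()]; an empty `weight` cell means
#' "derive from the category under `scheme`", a filled cell is an explicit
#' per-edge override that survives [apply_scheme()].
#'
#' @param path File path.
#' @param scheme A [weight_scheme()] used for rows without an explicit weight.
#' @return `read_kn()` returns a validated [knowledge_network()];
#'   `write_kn()` returns `path` invisibly. Writing then reading a network
#'   reproduces its nodes, edges and weights exactly.
#' @export
read_kn <- function(path, scheme = scheme_from_label("<137>")) {
  if (!file.exists(path)) {
    rlang::abort(paste0("KN file not found: ", path), class = "dxr_io_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) <= 1) {
    return(knowledge_network(scheme = scheme))
  }
  missing_cols <- setdiff(setdiff(.kn_header, "weight"), names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0("KN TSV is missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "dxr_parse_error")
  }
  if (!"weight" %in% names(raw)) raw$weight <- NA_character_
  bad <- which(is.na(raw$finding_id) | is.na(raw$disease_id) | is.na(raw$category))
  if (length(bad)) {
    rlang::abort(paste0("malformed KN row at line ", bad[1] + 1L,
                        " (missing finding_id, disease_id or category)"),
                 class = "dxr_parse_error")
  }
  w <- suppressWarnings(as.numeric(raw$weight))
  bad_w <- which(!is.na(raw$weight) & raw$weight != "" & is.na(w))
  if (length(bad_w)) {
    rlang::abort(paste0("non-numeric weight at line ", bad_w[1] + 1L),
                 class = "dxr_parse_error")
  }
  knowledge_network(
    diseases = dplyr::distinct(tibble::tibble(
      disease_id = raw$disease_id, disease_name = raw$disease_name)),
    findings = dplyr::distinct(tibble::tibble(
      finding_id = raw$finding_id, finding_name = raw$finding_name)),
    edges = tibble::tibble(finding_id = raw$finding_id, disease_id = raw$disease_id,
                           category = raw$category, weight = w),
    scheme = scheme
  )
}

#' @rdname read_kn
#' @inheritParams validate_kn
#' @export
write_kn <- function(kn, path) {
  stopifnot(inherits(kn, "dxr_kn"))
  out <- kn$edges |>
    dplyr::left_join(kn$findings, by = "finding_id") |>
    dplyr::left_join(kn$diseases, by = "disease_id") |>
    dplyr::select(dplyr::all_of(.kn_header))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# finding -> adjacent diseases lookup, used by the matcher and simulator
kn_adjacency <- function(kn) {
  split(seq_len(nrow(kn$edges)), kn$edges$finding_id)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
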