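#' Category weight schemes for the knowledge network
#'
#' A weight scheme assigns one positive edge weight to each finding category:
#' occasional clinical manifestations, common clinical manifestations, and
#' auxiliary examination results. Auxiliary results are instrument-based and
#' carry the strongest diagnostic evidence, so the published schemes weight
#' them highest; the default scheme is `<137>` (occasional 1, common 3,
#' auxiliary 7).
#'
#' @param occasional,common,auxiliary Positive edge weights for the three
#'   finding categories.
#' @param name Short display label, e.g. `"<137>"`.
#' @return An object of class `dxr_weight_scheme`: a named list with elements
#'   `occasional`, `common`, `auxiliary` and `name`.
#' @examples
#' weight_scheme(1, 3, 7)
#' scheme_from_label("<135>")
#' scheme_from_label("2,4,8")
#' @export
weight_scheme <- function(occasional, common, auxiliary, name = NULL) {
  w <- c(occasional = occasional, common = common, auxiliary = auxiliary)
  if (!is.numeric(w) || length(w) != 3L || any(!is.finite(w)) || any(w <= 0)) {
    rlang::abort("all three scheme weights must be finite positive numbers",
                 class = "dxr_scheme_error")
  }
  if (is.null(name)) {
    name <- paste0("<", paste(format(unname(w), trim = TRUE), collapse = ""), ">")
  }
  structure(
    list(occasional = unname(occasional), common = unname(common),
         auxiliary = unname(auxiliary), name = name),
    class = "dxr_weight_scheme"
  )
}

# the five published weight-setting groups
.scheme_table <- list(
  "<113>" = c(1, 1, 3),
  "<123>" = c(1, 2, 3),
  "<135>" = c(1, 3, 5),
  "<137>" = c(1, 3, 7),
  "<139>" = c(1, 3, 9)
)

#' @rdname weight_scheme
#' @param label One of the published scheme labels (`"<113>"`, `"<123>"`,
#'   `"<135>"`, `"<137>"`, `"<139>"`) or a comma triple `"a,b,c"` giving
#'   occasional, common and auxiliary weights directly.
#' @export
scheme_from_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (label %in% names(.scheme_table)) {
    w <- .scheme_table[[label]]
    return(weight_scheme(w[1], w[2], w[3], name = label))
  }
  parts <- suppressWarnings(as.numeric(strsplit(label, ",", fixed = TRUE)[[1]]))
  if (length(parts) == 3L && !anyNA(parts)) {
    return(weight_scheme(parts[1], parts[2], parts[3],
                         name = paste0("<", gsub(",", "", label), ">")))
  }
  rlang::abort(
    paste0("unrecognized weight-scheme label ", encodeString(label, quote = '"'),
           "; valid labels: ", paste(names(.scheme_table), collapse = ", "),
           ', or a comma triple like "2,4,8"'),
    class = "dxr_usage_error"
  )
}

#' @export
print.dxr_weight_scheme <- function(x, ...) {
  cat(sprintf("<dxr_weight_scheme %s> occasional=%g common=%g auxiliary=%g\n",
              x$name, x$occasional, x$common, x$auxiliary))
  invisible(x)
}

# weight for a vector of categories under a scheme
scheme_weight <- function(scheme, category) {
  unlist(scheme[c("occasional", "common", "auxiliary")])[
    match(category, c("occasional", "common", "auxiliary"))]
}

#' Finding categories
#'
#' The closed set of diagnostic-indicator categories: `"occasional"` and
#' `"common"` clinical manifestations, and `"auxiliary"` examination results.
#'
#' @return A character vector of the three category tokens.
#' @export
finding_categories <- function() c("occasional", "common", "auxiliary")
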