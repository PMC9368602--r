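#' Linear-chain CRF scores
#'
#' Container for externally produced sequence-labelling scores: an `n x K`
#' emission matrix (one row per token, one column per tag) and a
#' `(K+2) x (K+2)` transition matrix whose last two states are the implicit
#' START (row/column `K+1`) and STOP (`K+2`) positions. Any upstream encoder
#' (e.g. a trained BiLSTM) can hand over these matrices and reuse
#' [crf_decode()]; no training is provided here.
#'
#' @param emissions Numeric `n x K` matrix of per-token tag scores.
#' @param transitions Numeric `(K+2) x (K+2)` matrix; `transitions[i, j]` is
#'   the score of moving from tag `i` to tag `j`.
#' @param labels Optional character vector of `K` tag names.
#' @return An object of class `dxr_crf`.
#' @export
crf_scores <- function(emissions, transitions, labels = NULL) {
  emissions <- as.matrix(emissions)
  transitions <- as.matrix(transitions)
  n <- nrow(emissions); K <- ncol(emissions)
  if (n < 1L || K < 1L) {
    rlang::abort("emissions must have >= 1 row and >= 1 column",
                 class = "dxr_contract_error")
  }
  if (!all(dim(transitions) == K + 2L)) {
    rlang::abort(sprintf("transitions must be %d x %d (K tags + START + STOP)",
                         K + 2L, K + 2L), class = "dxr_contract_error")
  }
  if (any(!is.finite(emissions)) || any(!is.finite(transitions))) {
    rlang::abort("scores must be finite", class = "dxr_contract_error")
  }
  if (!is.null(labels) && length(labels) != K) {
    rlang::abort("labels must have length K", class = "dxr_contract_error")
  }
  structure(list(emissions = emissions, transitions = transitions,
                 labels = labels, n = n, K = K),
            class = "dxr_crf")
}

#' @export
print.dxr_crf <- function(x, ...) {
  cat(sprintf("<dxr_crf> n=%d tokens, K=%d tags%s\n", x$n, x$K,
              if (!is.null(x$labels)) paste0(" (", paste(x$labels, collapse = ","), ")") else ""))
  invisible(x)
}

# resolve a tag sequence (labels or indices) to 1-based indices
crf_tag_indices <- function(scores, tags) {
  if (is.character(tags)) {
    if (is.null(scores$labels)) {
      rlang::abort("character tags need labelled scores", class = "dxr_contract_error")
    }
    idx <- match(tags, scores$labels)
  } else {
    idx <- as.integer(tags)
  }
  if (length(idx) != scores$n) {
    rlang::abort("tag sequence length must equal the emission row count",
                 class = "dxr_contract_error")
  }
  if (anyNA(idx) || any(idx < 1L | idx > scores$K)) {
    rlang::abort("invalid tag index", class = "dxr_contract_error")
  }
  idx
}

#' Path score of a tag sequence
#'
#' The linear-chain score
#' `s(X, Y) = A[START, y1] + sum_i A[y_i, y_{i+1}] + A[y_n, STOP] + sum_i P[i, y_i]`,
#' summing transition scores along the path (including the implicit START and
#' STOP moves) and the emission score of each chosen tag.
#'
#' @param scores A [crf_scores()] object.
#' @param tags Tag sequence: integer indices in `1..K` or labels.
#' @return A single numeric score.
#' @export
crf_score <- function(scores, tags) {
  stopifnot(inherits(scores, "dxr_crf"))
  y <- crf_tag_indices(scores, tags)
  n <- scores$n; K <- scores$K
  A <- scores$transitions; P <- scores$emissions
  start <- K + 1L; stop_ <- K + 2L
  trans <- A[start, y[1]] + A[y[n], stop_]
  if (n > 1L) trans <- trans + sum(A[cbind(y[-n], y[-1])])
  trans + sum(P[cbind(seq_len(n), y)])
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log-partition over all K^n tag sequences, forward algorithm in log space
crf_log_partition <- function(scores) {
  n <- scores$n; K <- scores$K
  A <- scores$transitions; P <- scores$emissions
  start <- K + 1L; stop_ <- K + 2L
  alpha <- A[start, seq_len(K)] + P[1, ]
  if (n > 1L) {
    for (i in 2:n) {
      alpha <- vapply(seq_len(K), function(j) {
        logsumexp(alpha + A[seq_len(K), j]) + P[i, j]
      }, numeric(1))
    }
  }
  logsumexp(alpha + A[seq_len(K), stop_])
}

#' Log-likelihood of a tag sequence
#'
#' `log P(Y | X) = s(X, Y) - log sum_{Y~} exp(s(X, Y~))`, with the
#' log-partition computed by the forward algorithm in log space, so
#' `exp()` of the result lies in `(0, 1]` and the probabilities of all `K^n`
#' sequences sum to one.
#'
#' @inheritParams crf_score
#' @return The log-probability of `tags`.
#' @export
crf_log_likelihood <- function(scores, tags) {
  crf_score(scores, tags) - crf_log_partition(scores)
}

#' Viterbi decoding
#'
#' Returns the tag sequence maximizing [crf_score()]. Ties are broken towards
#' the lowest tag index at every backtracking step, so decoding is
#' deterministic.
#'
#' @param scores A [crf_scores()] object.
#' @return Integer tag indices, or tag labels if `scores$labels` is set.
#' @export
crf_decode <- function(scores) {
  stopifnot(inherits(scores, "dxr_crf"))
  n <- scores$n; K <- scores$K
  A <- scores$transitions; P <- scores$emissions
  start <- K + 1L; stop_ <- K + 2L
  delta <- A[start, seq_len(K)] + P[1, ]
  back <- matrix(0L, nrow = n, ncol = K)
  if (n > 1L) {
    for (i in 2:n) {
      new_delta <- numeric(K)
      for (j in seq_len(K)) {
        cand <- delta + A[seq_len(K), j]
        b <- which.max(cand)              # first maximum = lowest tag index
        back[i, j] <- b
        new_delta[j] <- cand[b] + P[i, j]
      }
      delta <- new_delta
    }
  }
  final <- delta + A[seq_len(K), stop_]
  y <- integer(n)
  y[n] <- which.max(final)
  if (n > 1L) {
    for (i in n:2) y[i - 1L] <- back[i, y[i]]
  }
  if (!is.null(scores$labels)) scores$labels[y] else y
}

#' Read CRF scores from JSON
#'
#' Expects `{"emissions": n x K array, "transitions": (K+2) x (K+2) array,
#' "labels": [tag names]}`.
#'
#' @param path JSON file path.
#' @return A [crf_scores()] object.
#' @export
read_crf_scores <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  crf_scores(obj$emissions, obj$transitions, labels = obj$labels)
}
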