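# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (dense linear algebra, explicit enumeration, per-record
# set arithmetic) and share no code with the package internals.

# dense fixed-point NodeRank: nr = (1-d) 1 + d * M' nr with
# M[u, v] = w(u, v) / outweight(u); solved directly.
oracle_noderank <- function(edges, d, nodes = NULL) {
  ids <- sort(unique(c(edges$from, edges$to, nodes)))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    M[edges$from[i], edges$to[i]] <- M[edges$from[i], edges$to[i]] + edges$weight[i]
  }
  outw <- rowSums(M)
  pos <- outw > 0
  M[pos, ] <- M[pos, , drop = FALSE] / outw[pos]
  nr <- solve(diag(n) - d * t(M), rep(1 - d, n))
  stats::setNames(as.numeric(nr), ids)
}

# all K^n tag sequences of a CRF instance, scored term by term
oracle_crf_all_scores <- function(sc) {
  n <- sc$n; K <- sc$K
  A <- sc$transitions; P <- sc$emissions
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  apply(grid, 1, function(y) {
    s <- A[K + 1L, y[1]] + A[y[n], K + 2L]
    if (n > 1) for (i in seq_len(n - 1)) s <- s + A[y[i], y[i + 1]]
    for (i in seq_len(n)) s <- s + P[i, y[i]]
    s
  })
}

random_crf <- function(n, K, labels = NULL) {
  crf_scores(matrix(rnorm(n * K), n, K),
             matrix(rnorm((K + 2)^2), K + 2, K + 2),
             labels = labels)
}

# naive per-record metric re-implementations over the same tibble shape
oracle_metrics <- function(preds, labels) {
  dense <- function(s) {
    v <- stats::setNames(rep(0, length(labels)), labels)
    v[intersect(names(s), labels)] <- s[intersect(names(s), labels)]
    v
  }
  Q <- length(labels)
  N <- nrow(preds)
  hl <- oe <- rl <- ap <- 0
  tp <- fp <- fn <- 0
  rl_n <- 0
  for (i in seq_len(N)) {
    p <- preds$predicted[[i]]; g <- preds$gold[[i]]
    s <- dense(preds$scores[[i]])
    hl <- hl + length(union(setdiff(p, g), setdiff(g, p))) / Q
    top <- names(s)[order(-s, names(s))][1]
    oe <- oe + as.numeric(!(top %in% g))
    comp <- setdiff(labels, g)
    if (length(comp)) {
      bad <- 0
      for (y in g) for (yb in comp) if (s[y] <= s[yb]) bad <- bad + 1
      rl <- rl + bad / (length(g) * length(comp))
      rl_n <- rl_n + 1
    }
    # total-order ranks: strictly greater score first, ties by label id
    ord <- order(-s, names(s))
    rank_of <- stats::setNames(match(names(s), names(s)[ord]), names(s))
    ap_i <- 0
    for (y in g) {
      r <- rank_of[y]
      ap_i <- ap_i + sum(rank_of[g] <= r) / r
    }
    ap <- ap + ap_i / length(g)
    tp <- tp + length(intersect(p, g))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  list(hamming_loss = hl / N, one_error = oe / N,
       ranking_loss = unname(rl / rl_n),
       average_precision = unname(ap / N),
       micro_precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       micro_recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       micro_f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0)
}

# random labelled-prediction corpus over Q labels
random_pred_corpus <- function(N, Q) {
  labels <- sprintf("L%02d", seq_len(Q))
  tibble::tibble(
    record_id = sprintf("r%03d", seq_len(N)),
    scores = lapply(seq_len(N), function(i) {
      k <- sample(0:Q, 1)
      stats::setNames(round(runif(k), 3), sample(labels, k))
    }),
    predicted = lapply(seq_len(N), function(i) sample(labels, sample(0:Q, 1))),
    gold = lapply(seq_len(N), function(i) sample(labels, sample(1:Q, 1)))
  )
}

# small random knowledge network built directly from tibbles (independent of
# the simulator) for round-trip and matching tests
random_kn <- function(n_diseases = 5, n_findings = 12,
                      scheme = scheme_from_label("<137>")) {
  d_ids <- sprintf("D%02d", seq_len(n_diseases))
  f_ids <- sprintf("F%02d", seq_len(n_findings))
  edges <- expand.grid(finding_id = f_ids, disease_id = d_ids,
                       stringsAsFactors = FALSE)
  attr(edges, "out.attrs") <- NULL
  edges <- edges[runif(nrow(edges)) < 0.3, , drop = FALSE]
  # keep every node incident to at least one edge (the TSV dialect stores
  # nodes through edges, so round-trips need no isolated nodes)
  missing_f <- setdiff(f_ids, edges$finding_id)
  missing_d <- setdiff(d_ids, edges$disease_id)
  extra <- data.frame(
    finding_id = c(missing_f, sample(f_ids, length(missing_d), replace = TRUE)),
    disease_id = c(sample(d_ids, length(missing_f), replace = TRUE), missing_d))
  edges <- unique(rbind(edges, extra))
  edges$category <- sample(finding_categories(), nrow(edges), replace = TRUE)
  knowledge_network(
    diseases = data.frame(disease_id = d_ids, disease_name = paste0("dis ", d_ids)),
    findings = data.frame(finding_id = f_ids, finding_name = paste0("sign ", f_ids)),
    edges = edges, scheme = scheme
  )
}

# random weighted digraph edge tibble (mixed cyclic/acyclic), n nodes
random_digraph <- function(n_nodes, p_edge = 0.15) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  grid <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to & runif(nrow(grid)) < p_edge, , drop = FALSE]
  if (nrow(grid) == 0) grid <- data.frame(from = ids[1], to = ids[2])
  grid$weight <- runif(nrow(grid), 0.1, 5)
  tibble::as_tibble(grid)
}
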