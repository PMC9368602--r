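perfect_corpus <- function(N = 8, Q = 6) {
  labels <- sprintf("L%02d", seq_len(Q))
  gold <- lapply(seq_len(N), function(i) sample(labels, sample(1:(Q - 1), 1)))
  tibble::tibble(
    record_id = sprintf("r%02d", seq_len(N)),
    scores = lapply(gold, function(g) {
      stats::setNames(c(runif(length(g), 0.6, 1), rep(0, 0)), g)
    }),
    predicted = gold,
    gold = gold
  )
}

test_that("hand-checkable metric values are exact", {
  labels <- c("a", "b", "c", "d")
  preds <- tibble::tibble(
    record_id = "r1",
    scores = list(c(a = 0.9, b = 0.1)),
    predicted = list("a"),
    gold = list(c("a", "b"))
  )
  expect_equal(hamming_loss(preds, labels), 0.25)          # |Δ|=1 of Q=4
  expect_equal(one_error(preds, labels), 0)                # top label a is gold
  # single gold label ranked k-th of Q: AP = mean over golds of precision@rank
  preds2 <- tibble::tibble(
    record_id = "r1",
    scores = list(c(a = 0.9, b = 0.8, c = 0.7)),
    predicted = list("c"),
    gold = list("c")
  )
  expect_equal(average_precision(preds2, labels), 1 / 3)
  # printed-variant normalization divides by Q instead of |gold|
  expect_equal(average_precision(preds2, labels, normalize = "label_space"),
               (1 / 3) / 4)
})

test_that("perfect predictions hit the forced extremes", {
  withr::with_seed(51, {
    preds <- perfect_corpus()
    labels <- sprintf("L%02d", 1:6)
    expect_equal(hamming_loss(preds, labels), 0)
    expect_equal(one_error(preds, labels), 0)
    expect_equal(ranking_loss(preds, labels), 0)
    expect_equal(average_precision(preds, labels), 1)
    mf <- micro_f1(preds, labels)
    expect_equal(unlist(mf), c(micro_precision = 1, micro_recall = 1, micro_f1 = 1))
  })
})

test_that("all-tied scores force ranking loss 1; empty predictions give F1 0", {
  labels <- c("a", "b", "c")
  preds <- tibble::tibble(
    record_id = c("r1", "r2"),
    scores = list(c(a = 0.5, b = 0.5, c = 0.5), c()),
    predicted = list(character(0), character(0)),
    gold = list("a", c("b", "c"))
  )
  expect_equal(ranking_loss(preds, labels), 1)   # every pair ties, ties count
  expect_warning(mf <- micro_f1(preds, labels), regexp = "zero denominator")
  expect_equal(mf$micro_precision, 0)
  expect_equal(mf$micro_recall, 0)
  expect_equal(mf$micro_f1, 0)
  # top label never in gold -> one-error 1
  preds_oe <- tibble::tibble(
    record_id = "r1", scores = list(c(a = 1)),
    predicted = list("a"), gold = list("b")
  )
  expect_equal(one_error(preds_oe, labels), 1)
})

test_that("a record whose gold set covers the label space is skipped in RL", {
  labels <- c("a", "b")
  preds <- tibble::tibble(
    record_id = c("r1", "r2"),
    scores = list(c(a = 1, b = 0.5), c(a = 0.2, b = 0.6)),
    predicted = list("a", "b"),
    gold = list(c("a", "b"), "b")
  )
  expect_warning(rl <- ranking_loss(preds, labels), regexp = "skipped")
  expect_equal(rl, 0)  # the surviving record ranks its gold label first
})

test_that("all five metrics equal naive re-implementations on random corpora", {
  withr::with_seed(52, {
    for (rep in 1:60) {
      N <- sample(2:50, 1); Q <- sample(2:12, 1)
      preds <- random_pred_corpus(N, Q)
      labels <- sprintf("L%02d", seq_len(Q))
      full_gold <- vapply(preds$gold, function(g) length(g) == Q, logical(1))
      oracle <- oracle_metrics(preds, labels)
      expect_equal(hamming_loss(preds, labels), oracle$hamming_loss)
      expect_equal(one_error(preds, labels), oracle$one_error)
      if (any(full_gold)) {
        expect_warning(rl <- ranking_loss(preds, labels))
      } else {
        rl <- ranking_loss(preds, labels)
      }
      if (!all(full_gold)) expect_equal(rl, oracle$ranking_loss)
      expect_equal(average_precision(preds, labels), oracle$average_precision)
      mf <- suppressWarnings(micro_f1(preds, labels))
      expect_equal(mf$micro_precision, oracle$micro_precision)
      expect_equal(mf$micro_recall, oracle$micro_recall)
      expect_equal(mf$micro_f1, oracle$micro_f1)
    }
  })
})

test_that("ranking metrics are invariant to record order and monotone transforms", {
  withr::with_seed(53, {
    preds <- random_pred_corpus(20, 8)
    labels <- sprintf("L%02d", 1:8)
    shuffled <- preds[sample(nrow(preds)), ]
    transformed <- preds
    transformed$scores <- lapply(preds$scores, function(s) exp(3 * s) + 1)
    for (f in list(hamming_loss, one_error, average_precision)) {
      expect_equal(f(shuffled, labels), f(preds, labels))
      expect_equal(f(transformed, labels), f(preds, labels))
    }
    expect_equal(suppressWarnings(ranking_loss(shuffled, labels)),
                 suppressWarnings(ranking_loss(preds, labels)))
    expect_equal(suppressWarnings(ranking_loss(transformed, labels)),
                 suppressWarnings(ranking_loss(preds, labels)))
  })
})

test_that("scrambled scores drive AP towards the random-ranking expectation", {
  withr::with_seed(54, {
    Q <- 10; N <- 400
    labels <- sprintf("L%02d", seq_len(Q))
    gold <- lapply(seq_len(N), function(i) sample(labels, 3))
    preds <- tibble::tibble(
      record_id = sprintf("r%03d", seq_len(N)),
      scores = lapply(seq_len(N), function(i) stats::setNames(runif(Q), labels)),
      predicted = gold, gold = gold
    )
    # permutation oracle: expected AP of a uniformly random ranking
    perm_ap <- mean(replicate(2000, {
      r <- sort(sample(Q, 3))
      mean(vapply(seq_along(r), function(j) sum(r <= r[j]) / r[j], numeric(1)))
    }))
    expect_equal(average_precision(preds, labels), perm_ap, tolerance = 0.05)
  })
})

test_that("k-fold splits are disjoint, covering and balanced", {
  folds <- kfold_split(sprintf("r%02d", 1:10), k = 5, seed = 1)
  expect_equal(lengths(folds), rep(2L, 5), ignore_attr = TRUE)
  withr::with_seed(55, {
    for (rep in 1:10) {
      n <- sample(5:200, 1); k <- sample(2:5, 1)
      if (k > n) next
      ids <- sprintf("r%04d", seq_len(n))
      folds <- kfold_split(ids, k = k, seed = rep)
      expect_setequal(unlist(folds), ids)
      expect_equal(sum(lengths(folds)), n)          # disjoint + covering
      expect_lte(diff(range(lengths(folds))), 1)
    }
  })
  expect_error(kfold_split(letters[1:3], k = 4, seed = 1),
               class = "dxr_contract_error")
  # same seed, same split
  expect_equal(kfold_split(letters, 5, seed = 9), kfold_split(letters, 5, seed = 9))
})

test_that("evaluation reports aggregate and tidy correctly", {
  withr::with_seed(56, {
    preds <- perfect_corpus(N = 6, Q = 5)
    rep <- evaluate_predictions(preds, labels = sprintf("L%02d", 1:5))
    expect_s3_class(rep, "dxr_metrics")
    expect_equal(rep$micro_f1, 1)
    expect_equal(rep$n_records, 6)
    td <- tidy(rep)
    expect_equal(nrow(td), 7)
    expect_true(all(c("metric", "value") %in% names(td)))
    gl <- glance(rep)
    expect_equal(gl$q_labels, 5)
  })
  expect_error(evaluate_predictions(tibble::tibble()), class = "dxr_contract_error")
})
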