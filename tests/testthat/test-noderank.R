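nr_lookup <- function(ranks, node) ranks$nr[ranks$node == node]

test_that("closed forms hold on the two-node calibration chain", {
  edges <- tibble::tibble(from = "GOLD", to = "STD", weight = 7)
  ranks <- noderank_scores(edges, d = 0.85)
  expect_equal(nr_lookup(ranks, "GOLD"), 0.15)
  expect_equal(nr_lookup(ranks, "STD"), 0.15 + 0.85 * 0.15)
})

test_that("the bipartite worked example reproduces hand-computed scores", {
  edges <- tibble::tibble(from = c("f1", "f2", "f2"), to = c("A", "A", "B"),
                          weight = 3)
  ranks <- noderank_scores(edges, d = 0.85)
  expect_equal(nr_lookup(ranks, "A"), 0.15 + 0.85 * (0.15 * 1 + 0.15 * 0.5))
  expect_equal(nr_lookup(ranks, "B"), 0.15 + 0.85 * 0.15 * 0.5)
  # and matches the dense fixed-point oracle
  oracle <- oracle_noderank(edges, d = 0.85)
  expect_equal(stats::setNames(ranks$nr, ranks$node)[names(oracle)], oracle,
               tolerance = 1e-9)
})

test_that("scores match a dense fixed-point oracle on random digraphs", {
  withr::with_seed(41, {
    for (rep in 1:30) {
      edges <- random_digraph(sample(5:30, 1))
      for (d in c(0.5, 0.85)) {
        ranks <- noderank_scores(edges, d = d, max_iter = 500)
        oracle <- oracle_noderank(edges, d = d)
        got <- stats::setNames(ranks$nr, ranks$node)[names(oracle)]
        expect_equal(got, oracle, tolerance = 1e-9)
      }
    }
  })
})

test_that("sources converge to 1-d and parameter contracts are enforced", {
  edges <- tibble::tibble(from = c("a", "b"), to = c("c", "c"), weight = c(1, 2))
  ranks <- noderank_scores(edges, d = 0.7)
  expect_equal(nr_lookup(ranks, "a"), 0.3)
  expect_equal(nr_lookup(ranks, "b"), 0.3)
  expect_error(noderank_scores(edges, d = 1), class = "dxr_contract_error")
  expect_error(noderank_scores(edges, d = 0), class = "dxr_contract_error")
  expect_error(noderank_scores(tibble::tibble(from = "a", to = "b", weight = -1)),
               class = "dxr_contract_error")
  # a fed cycle contracts only geometrically; a tiny iteration cap must
  # report non-convergence rather than return a bad fixed point
  cyc <- tibble::tibble(from = c("s", "a", "b"), to = c("a", "b", "a"),
                        weight = 1)
  expect_error(noderank_scores(cyc, max_iter = 2L), class = "dxr_convergence_error")
  # isolated nodes passed via `nodes` score 1-d
  r2 <- noderank_scores(edges, d = 0.85, nodes = "iso")
  expect_equal(nr_lookup(r2, "iso"), 0.15)
})

simple_kn <- function(edges_df, scheme = scheme_from_label("<137>")) {
  knowledge_network(
    diseases = data.frame(disease_id = unique(edges_df$disease_id)),
    findings = data.frame(finding_id = unique(edges_df$finding_id)),
    edges = edges_df, scheme = scheme
  )
}

test_that("prediction thresholds at the standard disease score, inclusively", {
  kn <- simple_kn(data.frame(finding_id = c("f1", "f2", "f2"),
                             disease_id = c("A", "A", "B"),
                             category = "common"))
  sub <- build_subnetwork("r", c("f1", "f2"), kn)
  r <- predict(sub, d = 0.85)
  expect_equal(r$threshold, 0.15 * 1.85, tolerance = 1e-12)
  expect_equal(r$predicted, "A")
  # empty evidence: nothing can reach the threshold
  r0 <- predict(build_subnetwork("r0", character(), kn))
  expect_equal(r0$predicted, character(0))
  # one exclusive auxiliary finding puts a disease exactly AT the threshold:
  # the >= contract includes it
  kn2 <- simple_kn(data.frame(finding_id = "ax", disease_id = "C",
                              category = "auxiliary"))
  r2 <- predict(build_subnetwork("r2", "ax", kn2))
  expect_equal(r2$scores$nr, r2$threshold)
  expect_equal(r2$predicted, "C")
})

test_that("support ratio reproduces the prediction rule", {
  kn <- simple_kn(data.frame(finding_id = c("f1", "f2", "f2"),
                             disease_id = c("A", "A", "B"),
                             category = "common"))
  sub <- build_subnetwork("r", c("f1", "f2"), kn)
  expect_equal(support_ratio(sub, "A"), 1.5)
  expect_equal(support_ratio(sub, "B"), 0.5)
  expect_error(support_ratio(sub, "nope"), class = "dxr_contract_error")
  # cross-operation equivalence on random subnetworks and dampings
  withr::with_seed(42, {
    for (rep in 1:15) {
      knr <- random_kn(n_diseases = 6, n_findings = 14)
      picked <- sample(knr$findings$finding_id, sample(1:7, 1))
      subr <- build_subnetwork("r", picked, knr)
      dis <- subr$nodes$id[subr$nodes$type == "disease"]
      for (d in c(0.5, 0.85, 0.99)) {
        pr <- predict(subr, d = d)
        by_ratio <- dis[vapply(dis, function(x) support_ratio(subr, x), numeric(1)) >= 1]
        expect_setequal(pr$predicted, by_ratio)
        expect_equal(pr$threshold, (1 - d) * (1 + d), tolerance = 1e-12)
      }
    }
  })
})

test_that("bipartite subnetwork scores equal the closed form after two sweeps", {
  withr::with_seed(43, {
    kn <- random_kn(n_diseases = 5, n_findings = 12)
    picked <- sample(kn$findings$finding_id, 5)
    sub <- build_subnetwork("r", picked, kn)
    d <- 0.85
    pr <- predict(sub, d = d)
    for (i in seq_len(nrow(pr$scores))) {
      sr <- support_ratio(sub, pr$scores$disease_id[i])
      expect_equal(pr$scores$nr[i], (1 - d) + d * (1 - d) * sr, tolerance = 1e-12)
    }
    # iterating to convergence and a single application coincide here:
    # two-sweep closed form IS the fixed point (checked vs the dense oracle)
    oracle <- oracle_noderank(sub$edges, d = d, nodes = sub$nodes$id)
    got <- noderank_scores(sub, d = d)
    expect_equal(stats::setNames(got$nr, got$node)[names(oracle)], oracle,
                 tolerance = 1e-9)
  })
})

test_that("NodeRank is monotone in added support and invariant to weight scale", {
  kn <- simple_kn(data.frame(finding_id = c("f1", "f2", "f2"),
                             disease_id = c("A", "A", "B"),
                             category = "common"))
  sub <- build_subnetwork("r", c("f1", "f2"), kn)
  base_b <- predict(sub)$scores
  # add a new finding supporting B only
  kn2 <- simple_kn(data.frame(finding_id = c("f1", "f2", "f2", "f3"),
                              disease_id = c("A", "A", "B", "B"),
                              category = "common"))
  sub2 <- build_subnetwork("r", c("f1", "f2", "f3"), kn2)
  more_b <- predict(sub2)$scores
  expect_gte(more_b$nr[more_b$disease_id == "B"],
             base_b$nr[base_b$disease_id == "B"])
  # scaling every weight by c > 0 changes nothing
  sub3 <- sub
  sub3$edges$weight <- sub3$edges$weight * 17.3
  expect_equal(predict(sub3)$scores, predict(sub)$scores, tolerance = 1e-12)
  expect_equal(predict(sub3)$predicted, predict(sub)$predicted)
})

test_that("negated mentions never influence the subnetwork", {
  kn <- simple_kn(data.frame(finding_id = c("f1", "f2"),
                             disease_id = c("A", "B"), category = "auxiliary"))
  records <- tibble::tibble(
    record_id = "r1",
    mentions = list(tibble::tibble(finding_id = c("f1", "f2"),
                                   surface = c("f1", "f2"),
                                   negated = c(FALSE, TRUE)))
  )
  preds <- predict_records(records, kn)
  expect_equal(preds$predicted[[1]], "A")
  expect_false("B" %in% names(preds$scores[[1]]))
})
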