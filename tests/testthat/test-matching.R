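test_that("bigram Dice similarity matches a set-arithmetic oracle", {
  expect_equal(string_similarity("腹痛", "腹痛"), 1.0)
  expect_equal(string_similarity("abcd", "wxyz"), 0.0)
  # explicit bigram-set computation for the classic near-synonym pair
  bigrams <- function(x) {
    ch <- strsplit(x, "")[[1]]
    unique(paste0(ch[-length(ch)], ch[-1]))
  }
  a <- "腹部疼痛"; b <- "腹痛"
  expected <- 2 * length(intersect(bigrams(a), bigrams(b))) /
    (length(bigrams(a)) + length(bigrams(b)))
  expect_equal(string_similarity(a, b), expected)
  # symmetry, and the single-character fallback
  expect_equal(string_similarity("ab", "ba"), string_similarity("ba", "ab"))
  expect_equal(string_similarity("痛", "痛"), 1.0)
  expect_equal(string_similarity("痛", "胀"), 0.0)
  expect_error(string_similarity("", "x"), class = "dxr_contract_error")
})

make_match_kn <- function() {
  knowledge_network(
    diseases = data.frame(disease_id = c("D1", "D2")),
    findings = data.frame(finding_id = c("F1", "F2", "F3"),
                          finding_name = c("腹痛", "腹痛待查", "恶心")),
    edges = data.frame(finding_id = c("F1", "F2", "F3"),
                       disease_id = c("D1", "D1", "D2"),
                       category = "common")
  )
}

test_that("exact surfaces win; below-threshold mentions stay unmatched", {
  kn <- make_match_kn()
  res <- match_findings(tibble::tibble(surface = "腹痛", polarity = "affirmed"), kn)
  expect_equal(res$method, "exact")
  expect_equal(res$finding_id, "F1")
  expect_equal(res$similarity, 1)
  res2 <- match_findings(tibble::tibble(surface = "qqqq", polarity = "affirmed"), kn)
  expect_equal(res2$method, "unmatched")
  expect_true(is.na(res2$finding_id))
  # negated mentions are a contract violation: the caller filters them
  expect_error(match_findings(tibble::tibble(surface = "腹痛", polarity = "negated"), kn),
               class = "dxr_contract_error")
})

test_that("similarity matching picks the best finding with deterministic ties", {
  kn <- make_match_kn()
  res <- match_findings(tibble::tibble(surface = "腹痛查", polarity = "affirmed"),
                        kn, threshold = 0.3)
  # exhaustive scoring oracle over all findings
  sims <- vapply(kn$findings$finding_name, string_similarity, numeric(1), a = "腹痛查")
  expect_equal(res$similarity, max(sims))
  expect_equal(res$method, "similarity")
  # tie: two findings with identical similarity -> shorter name wins
  kn2 <- knowledge_network(
    diseases = data.frame(disease_id = "D1"),
    findings = data.frame(finding_id = c("FA", "FB"),
                          finding_name = c("abcde", "ab")),
    edges = data.frame(finding_id = c("FA", "FB"), disease_id = "D1",
                       category = "common")
  )
  sims2 <- vapply(kn2$findings$finding_name, string_similarity, numeric(1), a = "abc")
  expect_equal(sims2[["abcde"]], sims2[["ab"]])
  res2 <- match_findings(tibble::tibble(surface = "abc", polarity = "affirmed"),
                         kn2, threshold = 0.1)
  expect_equal(res2$finding_id, "FB")
  # threshold 1.0 reduces to exact matching only
  res3 <- match_findings(tibble::tibble(surface = "腹痛查", polarity = "affirmed"),
                         kn, threshold = 1.0)
  expect_equal(res3$method, "unmatched")
})

test_that("subnetworks contain exactly the matched findings, their diseases and the gold pair", {
  kn <- make_match_kn()
  # zero matches: only the calibration pair remains
  sub0 <- build_subnetwork("r0", character(), kn)
  expect_equal(sort(sub0$nodes$id), sort(c(gold_standard_id(), standard_disease_id())))
  expect_equal(nrow(sub0$edges), 1L)
  expect_equal(sub0$edges$weight, kn$scheme$auxiliary)
  # one finding adjacent to one disease, plus pair: 2 edges
  sub1 <- build_subnetwork("r1", "F3", kn)
  expect_setequal(sub1$nodes$id, c("F3", "D2", gold_standard_id(), standard_disease_id()))
  expect_equal(nrow(sub1$edges), 2L)
  # repeated matches collapse to one finding node
  m <- tibble::tibble(surface = c("腹痛", "腹痛"), finding_id = c("F1", "F1"),
                      method = "exact", similarity = 1)
  sub2 <- build_subnetwork("r2", m, kn)
  expect_equal(sum(sub2$nodes$type == "finding"), 1L)
})

test_that("subnetwork disease sets equal brute-force KN neighborhoods", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      kn <- random_kn(n_diseases = 6, n_findings = 14)
      picked <- sample(kn$findings$finding_id, sample(1:6, 1))
      sub <- build_subnetwork("r", picked, kn)
      expected <- unique(kn$edges$disease_id[kn$edges$finding_id %in% picked])
      expect_setequal(sub$nodes$id[sub$nodes$type == "disease"], expected)
      # edge weights are a sub-multiset of KN weights plus exactly one gold edge
      gold <- sub$edges$from == gold_standard_id()
      expect_equal(sum(gold), 1L)
      kn_w <- sort(kn$edges$weight[kn$edges$finding_id %in% picked])
      expect_equal(sort(sub$edges$weight[!gold]), kn_w)
    }
  })
})

test_that("reserved node ids cannot collide with KN ids", {
  expect_error(
    knowledge_network(
      diseases = data.frame(disease_id = standard_disease_id()),
      findings = data.frame(finding_id = "F1"),
      edges = data.frame(finding_id = "F1", disease_id = standard_disease_id(),
                         category = "common")),
    class = "dxr_validation_error"
  )
})

test_that("subnetwork JSON dumps carry nodes and weighted edge triples", {
  kn <- make_match_kn()
  sub <- build_subnetwork("r1", c("F1", "F3"), kn)
  path <- withr::local_tempfile(fileext = ".json")
  write_subnetwork(sub, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$record_id, "r1")
  expect_setequal(obj$nodes$id, sub$nodes$id)
  expect_equal(nrow(obj$edges), nrow(sub$edges))
})
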