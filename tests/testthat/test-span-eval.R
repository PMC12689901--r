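test_that("granularity definitions separate boundary and type agreement", {
  g <- clin_spans("d", 0, 7, "SYMPTOM")

  identical_pred <- clin_spans("d", 0, 7, "SYMPTOM")
  for (gr in granularities()) {
    expect_equal(unname(match_spans(g, identical_pred, gr)$counts["COR"]), 1L)
  }

  wrong_type <- clin_spans("d", 0, 7, "ANATOMY")
  strict <- match_spans(g, wrong_type, "STRICT")
  expect_equal(unname(strict$counts[c("COR", "INC")]), c(0L, 1L))
  expect_equal(unname(match_spans(g, wrong_type, "EXACT")$counts["COR"]), 1L)
  expect_equal(unname(match_spans(g, wrong_type, "TYPE")$counts["COR"]), 0L)

  g10 <- clin_spans("d", 0, 10, "SYMPTOM")
  inside <- clin_spans("d", 3, 8, "SYMPTOM")
  expect_equal(unname(match_spans(g10, inside, "PARTIAL")$counts["PAR"]), 1L)
  expect_equal(unname(match_spans(g10, inside, "STRICT")$counts[c("MIS", "SPU")]),
               c(1L, 1L))
  expect_equal(unname(match_spans(g10, inside, "TYPE")$counts["COR"]), 1L)
})

test_that("match counts partition gold and prediction sides", {
  local_seed(303L)
  for (case in 1:50) {
    gold <- random_spans()
    pred <- random_spans()
    for (gr in granularities()) {
      ct <- match_spans(gold, pred, gr)$counts
      expect_equal(unname(ct["COR"] + ct["INC"] + ct["PAR"] + ct["MIS"]), nrow(gold))
      expect_equal(unname(ct["COR"] + ct["INC"] + ct["PAR"] + ct["SPU"]), nrow(pred))
    }
  }
})

test_that("mixed documents and duplicate triples are rejected", {
  g <- clin_spans(c("a", "b"), c(0, 0), c(5, 5), "SYMPTOM")
  expect_error(match_spans(g, clin_spans(), "STRICT"), "one document",
               class = "clinspan_validation_error")
  dup <- clin_spans("a", c(0, 0), c(5, 5), "SYMPTOM")
  expect_error(match_spans(dup, clin_spans(), "STRICT"), "duplicate",
               class = "clinspan_validation_error")
})

test_that("precision/recall/F1 follow the partial-credit formulas", {
  m <- compute_metrics(c(COR = 3, INC = 1, PAR = 2, MIS = 1, SPU = 2))
  expect_equal(m$precision, (3 + 0.5 * 2) / (3 + 1 + 2 + 2))
  expect_equal(m$recall, (3 + 0.5 * 2) / (3 + 1 + 2 + 1))
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_false(m$flagged)

  full <- compute_metrics(c(COR = 0, INC = 0, PAR = 2, MIS = 0, SPU = 0),
                          partial_credit = 1)
  expect_equal(full$precision, 1)

  zero <- compute_metrics(c(COR = 0, INC = 0, PAR = 0, MIS = 0, SPU = 0))
  expect_equal(c(zero$precision, zero$recall, zero$f1), c(0, 0, 0))
  expect_true(zero$flagged)
})

test_that("the assignment achieves the exhaustive optimum on small documents", {
  local_seed(2024L)
  for (case in 1:200) {
    gold <- random_spans()
    pred <- random_spans()
    for (gr in granularities()) {
      expect_equal(match_credit(match_spans(gold, pred, gr)),
                   oracle_best_credit(gold, pred, gr),
                   info = sprintf("case %d, %s", case, gr))
    }
  }
})

test_that("evaluate_corpus scores identity as all ones and empty predictions as zero recall", {
  corpus <- generate_corpus(generator_config(n_documents = 15L, seed = 8L))
  self <- evaluate_corpus(corpus, corpus)
  expect_true(all(self$f1 == 1))
  expect_true(all(self$precision == 1))
  expect_equal(self$support[self$label == "ALL"][1], nrow(corpus$spans))

  none <- evaluate_corpus(corpus, clin_spans())
  expect_true(all(none$recall == 0))
  expect_true(all(none$flagged))
})

test_that("evaluate_corpus rejects predictions for unknown documents", {
  corpus <- generate_corpus(generator_config(n_documents = 3L, seed = 8L))
  stray <- clin_spans("ghost", 0, 3, "SYMPTOM")
  expect_error(evaluate_corpus(corpus, stray), "ghost",
               class = "clinspan_validation_error")
})

test_that("corruption by misses alone lowers recall, not precision", {
  corpus <- generate_corpus(generator_config(n_documents = 120L, seed = 21L))
  pred <- corrupt_annotations(corpus,
                              config = corruption_config(p_miss = 0.2, seed = 22L))
  rep <- evaluate_corpus(corpus, pred)
  all_rows <- rep[rep$label == "ALL", ]
  expect_true(all(all_rows$precision == 1))
  expect_true(all(abs(all_rows$recall - 0.8) < 0.05))
})

test_that("inter-annotator agreement is F1-symmetric with P and R exchanged", {
  corpus <- generate_corpus(generator_config(n_documents = 25L, seed = 31L))
  a <- corpus$spans
  b <- corrupt_annotations(corpus, config = corruption_config(
    p_miss = 0.1, p_shift = 0.15, p_type = 0.1, p_spurious = 0.3, seed = 32L))
  ## symmetry holds on the documents both annotators cover
  shared <- intersect(unique(a$doc_id), unique(b$doc_id))
  a2 <- a[a$doc_id %in% shared, , drop = FALSE]
  b2 <- b[b$doc_id %in% shared, , drop = FALSE]
  ab <- interannotator_agreement(a2, b2)
  ba <- interannotator_agreement(b2, a2)
  ord <- match(paste(ab$label, ab$granularity), paste(ba$label, ba$granularity))
  expect_equal(ab$f1, ba$f1[ord], tolerance = 1e-12)
  expect_equal(ab$precision, ba$recall[ord], tolerance = 1e-12)
  expect_equal(ab$recall, ba$precision[ord], tolerance = 1e-12)
})

test_that("an annotator adding spurious spans gets 10/12 precision, full recall", {
  docs <- clin_corpus("d", paste(rep("Fieber Husten", 10), collapse = " "))
  starts <- seq(0L, by = 14L, length.out = 10L)
  a <- clin_spans("d", starts, starts + 6L, "SYMPTOM")
  extra_starts <- c(7L, 21L)
  b <- rbind(a, clin_spans("d", extra_starts, extra_starts + 6L, "ANATOMY"))
  rep <- interannotator_agreement(a, b)
  strict_all <- rep[rep$label == "ALL" & rep$granularity == "STRICT", ]
  expect_equal(strict_all$precision, 10 / 12)
  expect_equal(strict_all$recall, 1)
})

test_that("report writers emit TSV/JSON twins with provenance headers", {
  corpus <- generate_corpus(generator_config(n_documents = 5L, seed = 41L))
  rep <- evaluate_corpus(corpus, corpus)
  base <- withr::local_tempfile()
  paths <- write_metric_report(rep, base, meta = list(seed = 7, config_hash = "abc"))
  tsv <- readLines(paths["tsv"])
  expect_true(any(grepl("^# seed: 7", tsv)))
  expect_true(any(grepl("^# config_hash: abc", tsv)))
  js <- jsonlite::fromJSON(paths["json"])
  expect_equal(js$meta$seed, 7)
  expect_equal(sort(unique(js$rows$metric)), c("f1", "precision", "recall"))
  wide <- report_f1_summary(rep)
  expect_equal(dim(wide), c(4L, 5L))
})
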