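test_that("generation is seed-deterministic and leaves the caller's RNG alone", {
  cfg <- generator_config(n_documents = 12L, seed = 7L)
  a <- generate_corpus(cfg)
  set.seed(1); before <- runif(1)
  set.seed(1)
  b <- generate_corpus(cfg)
  after <- runif(1)
  expect_identical(a$documents$text, b$documents$text)
  expect_identical(a$spans, b$spans)
  expect_equal(before, after)  # generator restored the RNG state
})

test_that("generated gold spans are valid and guideline-conformant", {
  corpus <- generate_corpus(generator_config(n_documents = 50L, seed = 13L))
  expect_equal(nrow(validate_spans(corpus$documents, corpus$spans)), 0L)
  expect_equal(nrow(lint_guidelines(corpus$documents, corpus$spans)), 0L)
})

test_that("non-conformant mode produces the violations the linter targets", {
  corpus <- generate_corpus(
    generator_config(n_documents = 60L, seed = 14L, p_compound = 1,
                     p_slash_list = 0.5),
    conformant = FALSE
  )
  findings <- lint_guidelines(corpus$documents, corpus$spans)
  expect_true(nrow(findings) > 0)
  expect_true(all(findings$rule_id %in% c("COMPOUND_SPLIT", "SLASH_LIST_MERGED")))
  expect_setequal(unique(findings$rule_id), c("COMPOUND_SPLIT", "SLASH_LIST_MERGED"))
})

test_that("p_negation = 0 yields a corpus without negation cues", {
  corpus <- generate_corpus(generator_config(n_documents = 40L, seed = 15L,
                                             p_negation = 0))
  expect_false("NEGATION" %in% corpus$spans$label)
  some <- generate_corpus(generator_config(n_documents = 40L, seed = 15L,
                                           p_negation = 0.8))
  expect_true("NEGATION" %in% some$spans$label)
})

test_that("zero corruption rates reproduce gold; p_miss = 1 drops everything", {
  corpus <- generate_corpus(generator_config(n_documents = 20L, seed = 16L))
  same <- corrupt_annotations(corpus, config = corruption_config(seed = 17L))
  key <- function(x) paste(x$doc_id, x$start, x$end, x$label)
  expect_identical(key(same), key(corpus$spans))
  gone <- corrupt_annotations(corpus,
                              config = corruption_config(p_miss = 1, seed = 17L))
  expect_equal(nrow(gone), 0L)
})

test_that("corruption is seed-deterministic", {
  corpus <- generate_corpus(generator_config(n_documents = 15L, seed = 18L))
  cfg <- corruption_config(p_miss = 0.2, p_shift = 0.2, p_type = 0.2,
                           p_spurious = 0.5, seed = 19L)
  expect_identical(corrupt_annotations(corpus, config = cfg),
                   corrupt_annotations(corpus, config = cfg))
})

test_that("p_shift = 1 turns every strict match into a partial overlap", {
  corpus <- generate_corpus(generator_config(n_documents = 80L, seed = 20L))
  pred <- corrupt_annotations(corpus,
                              config = corruption_config(p_shift = 1, seed = 21L))
  expect_equal(nrow(pred), nrow(corpus$spans))
  rep <- evaluate_corpus(corpus, pred)
  all_rows <- rep[rep$label == "ALL", ]
  expect_equal(all_rows$cor[all_rows$granularity == "STRICT"], 0)
  expect_equal(all_rows$par[all_rows$granularity == "PARTIAL"], nrow(corpus$spans))
  expect_equal(all_rows$cor[all_rows$granularity == "TYPE"], nrow(corpus$spans))
})

test_that("shifted spans stay token-aligned and overlap their source", {
  corpus <- generate_corpus(generator_config(n_documents = 40L, seed = 22L))
  pred <- corrupt_annotations(corpus,
                              config = corruption_config(p_shift = 1, seed = 23L))
  for (i in seq_len(nrow(corpus$documents))) {
    d <- corpus$documents$doc_id[i]
    edges <- with(tokenize(corpus$documents$text[i]), sort(unique(c(start, end))))
    pp <- pred[pred$doc_id == d, ]
    expect_true(all(pp$start %in% edges))
    expect_true(all(pp$end %in% edges))
    gg <- corpus$spans[corpus$spans$doc_id == d, ]
    ## every shifted span overlaps some gold span (its source)
    for (k in seq_len(nrow(pp))) {
      expect_true(any(gg$start < pp$end[k] & gg$end > pp$start[k]))
    }
  }
})

test_that("spurious spans never overlap gold spans", {
  corpus <- generate_corpus(generator_config(n_documents = 60L, seed = 24L))
  pred <- corrupt_annotations(corpus,
                              config = corruption_config(p_miss = 1, p_spurious = 1,
                                                         seed = 25L))
  for (k in seq_len(nrow(pred))) {
    gg <- corpus$spans[corpus$spans$doc_id == pred$doc_id[k], ]
    expect_false(any(gg$start < pred$end[k] & gg$end > pred$start[k]))
  }
})

test_that("expected metrics closed forms hit the hand-derivable values", {
  ident <- expected_metrics(corruption_config(), n_gold = 1000, n_documents = 100)
  expect_true(all(ident$precision == 1))
  expect_true(all(ident$recall == 1))
  expect_true(all(ident$f1 == 1))

  miss <- expected_metrics(corruption_config(p_miss = 0.2), 1000, 100)
  expect_true(all(miss$recall == 0.8))
  expect_true(all(miss$precision == 1))

  flip <- expected_metrics(corruption_config(p_type = 0.3), 1000, 100)
  expect_equal(flip$recall[flip$granularity == "STRICT"], 0.7)
  expect_equal(flip$recall[flip$granularity == "EXACT"], 1)
  expect_equal(flip$recall[flip$granularity == "PARTIAL"], 1)
  expect_equal(flip$recall[flip$granularity == "TYPE"], 0.7)

  shift <- expected_metrics(corruption_config(p_shift = 0.4), 1000, 100)
  expect_equal(shift$recall[shift$granularity == "STRICT"], 0.6)
  expect_equal(shift$recall[shift$granularity == "PARTIAL"], 0.8)
  expect_equal(shift$recall[shift$granularity == "TYPE"], 1)

  spur <- expected_metrics(corruption_config(p_spurious = 0.5), 1000, 100)
  expect_true(all(spur$recall == 1))
  expect_true(all(abs(spur$precision - 1000 / 1050) < 1e-12))
})

test_that("invalid corruption configurations are rejected", {
  expect_error(corruption_config(p_miss = 0.6, p_shift = 0.5),
               class = "clinspan_validation_error")
  expect_error(corruption_config(p_miss = -0.1),
               class = "clinspan_validation_error")
  expect_error(corruption_config(p_spurious = -1),
               class = "clinspan_validation_error")
})
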