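test_that("confidence filtering keeps scored spans above tau and flags unscored ones", {
  sp <- clin_spans("d", c(0, 7, 14), c(6, 13, 20), "SYMPTOM",
                   confidence = c(0.9, 0.4, NA))
  kept <- filter_confidence(sp, 0.5)
  expect_equal(kept$start, c(0L, 14L))
  expect_equal(kept$unscored, c(FALSE, TRUE))

  expect_equal(nrow(filter_confidence(sp, 0)), 3L)
  expect_error(filter_confidence(sp, 1.5), class = "clinspan_validation_error")

  all_unscored <- clin_spans("d", c(0, 7), c(6, 13), "SYMPTOM")
  kept2 <- filter_confidence(all_unscored, 0.7)
  expect_equal(nrow(kept2), 2L)
  expect_true(all(kept2$unscored))
})

test_that("affirmed sets shrink monotonically as tau rises", {
  local_seed(77L)
  corpus <- generate_corpus(generator_config(n_documents = 20L, seed = 78L))
  sp <- corpus$spans
  sp$confidence <- runif(nrow(sp))
  key <- function(r) paste(r$doc_id, r$start, r$end)
  prev <- NULL
  for (tau in c(0, 0.3, 0.6, 0.9)) {
    aff <- extract_affirmed(corpus$documents, sp,
                            postprocess_config(confidence_threshold = tau))
    if (!is.null(prev)) expect_true(all(key(aff) %in% prev))
    prev <- key(aff)
  }
})

test_that("a pre-posed cue negates coordinated symptoms within its clause", {
  txt <- "No dyspnea, no thoracic pain."
  sp <- clin_spans("d",
                   start = c(3L, 15L, 0L, 12L),
                   end = c(10L, 28L, 2L, 14L),
                   label = c("SYMPTOM", "SYMPTOM", "NEGATION", "NEGATION"),
                   surface = c("dyspnea", "thoracic pain", "No", "no"))
  out <- detect_negated(txt, sp)
  expect_true(all(out$negated[out$label == "SYMPTOM"]))

  ## one cue scoping over coordination: "No dyspnea, thoracic pain."
  txt2 <- "No dyspnea, thoracic pain."
  sp2 <- clin_spans("d", c(3L, 12L, 0L), c(10L, 25L, 2L),
                    c("SYMPTOM", "SYMPTOM", "NEGATION"))
  out2 <- detect_negated(txt2, sp2)
  expect_true(all(out2$negated[out2$label == "SYMPTOM"]))
})

test_that("clause boundaries block negation scope", {
  txt <- "Keine Übelkeit. Fieber."
  sp <- clin_spans("d", c(0, 6, 16), c(5, 14, 22),
                   c("NEGATION", "SYMPTOM", "SYMPTOM"))
  out <- detect_negated(txt, sp)
  expect_equal(out$negated[out$label == "SYMPTOM"], c(TRUE, FALSE))

  ## and a cue never reaches backwards
  txt2 <- "Fieber, keine Übelkeit."
  sp2 <- clin_spans("d", c(0, 8, 14), c(6, 13, 22),
                    c("SYMPTOM", "NEGATION", "SYMPTOM"))
  out2 <- detect_negated(txt2, sp2)
  expect_equal(out2$negated[out2$label == "SYMPTOM"], c(FALSE, TRUE))
})

test_that("symptoms beyond the token window stay affirmed", {
  txt <- "Keine akute schwere neue plötzliche Dyspnoe."
  sp <- clin_spans("d", c(0, 37), c(5, 44), c("NEGATION", "SYMPTOM"))
  out <- detect_negated(txt, sp)  # 4 tokens between cue and symptom > window 3
  expect_false(out$negated[out$label == "SYMPTOM"])
  wide <- detect_negated(txt, sp, postprocess_config(negation_window = 5L))
  expect_true(wide$negated[wide$label == "SYMPTOM"])
})

test_that("bare pain fuses with the neighboring anatomy, compounds stay untouched", {
  txt <- "Kopf Schmerzen seit Tagen."
  sp <- clin_spans("d", c(0, 5), c(4, 14), c("ANATOMY", "SYMPTOM"))
  out <- fuse_pain_anatomy(txt, sp)
  expect_equal(out$surface_out[out$label == "SYMPTOM"], "Kopfschmerzen")
  expect_true(out$fused[out$label == "SYMPTOM"])
  expect_true(out$consumed[out$label == "ANATOMY"])

  ## anatomy after the pain term works too
  txt2 <- "Schmerzen im Rücken."
  sp2 <- clin_spans("d", c(0, 13), c(9, 19), c("SYMPTOM", "ANATOMY"))
  out2 <- fuse_pain_anatomy(txt2, sp2)
  expect_equal(out2$surface_out[out2$label == "SYMPTOM"], "Rückenschmerzen")

  comp <- fuse_pain_anatomy("Kopfschmerzen.", clin_spans("d", 0, 13, "SYMPTOM",
                                                         surface = "Kopfschmerzen"))
  expect_equal(comp$surface_out, "Kopfschmerzen")
  expect_false(comp$fused)

  lone <- fuse_pain_anatomy("Schmerzen seit Tagen.",
                            clin_spans("d", 0, 9, "SYMPTOM", surface = "Schmerzen"))
  expect_equal(lone$surface_out, "Schmerzen")
  expect_true(lone$generic_pain)
})

test_that("a clause boundary blocks anatomy-pain fusion", {
  txt <- "Rücken. Schmerzen seit Tagen."
  sp <- clin_spans("d", c(0, 8), c(6, 17), c("ANATOMY", "SYMPTOM"))
  out <- fuse_pain_anatomy(txt, sp)
  expect_false(out$fused[out$label == "SYMPTOM"])
  expect_true(out$generic_pain[out$label == "SYMPTOM"])
})

test_that("surface standardization strips punctuation and recapitalizes", {
  expect_equal(standardize_surface(c("HUSTEN:", "fieber", "Husten")),
               c("Husten", "Fieber", "Husten"))
  expect_equal(standardize_surface("  thoracic   pain.  "), "Thoracic pain")
  expect_error(standardize_surface("..."), class = "clinspan_validation_error")
  expect_error(standardize_surface(""), class = "clinspan_validation_error")
})

test_that("dictionary normalization maps variants and keeps unknown terms", {
  expect_equal(normalize_symptom(c("Verstopfung", "Gehustet", "Xyzalgie")),
               c("Obstipation", "Husten", "Xyzalgie"))
  expect_equal(normalize_symptom("obstipation"), "Obstipation")
})

test_that("standardization and normalization are idempotent", {
  dict <- default_symptom_dictionary()
  terms <- c("HUSTEN:", "Verstopfung", "fieber", "Xyzalgie", "gehustet")
  std <- standardize_surface(terms)
  expect_identical(standardize_surface(std), std)
  norm <- normalize_symptom(std, dict)
  expect_identical(normalize_symptom(norm, dict), norm)
})

test_that("dictionary invariants are enforced at load time", {
  expect_error(
    read_symptom_dictionary(data.frame(
      canonical = c("Husten", "Dyspnoe"), variant = c("keuchen", "keuchen"))),
    "multiple canonicals", class = "clinspan_validation_error"
  )
  dict <- read_symptom_dictionary(list(Husten = c("husten", "gehustet")))
  expect_true("Husten" %in% dict$variant)  # canonical is its own variant
})

test_that("the worked-example narrative yields three affirmed, two negated records", {
  fx <- table2_fixture()
  all_rec <- extract_affirmed(fx$documents, fx$spans, include_negated = TRUE)
  expect_equal(nrow(all_rec), 5L)
  expect_equal(sum(all_rec$negated), 2L)
  affirmed <- extract_affirmed(fx$documents, fx$spans)
  expect_setequal(affirmed$standardized_term,
                  c("Swelling", "Redness", "Overheating"))
  expect_setequal(all_rec$standardized_term[all_rec$negated],
                  c("Dyspnea", "Thoracic pain"))
})

test_that("record count is conserved: affirmed + negated = filtered symptom spans", {
  local_seed(55L)
  corpus <- generate_corpus(generator_config(n_documents = 30L, seed = 56L))
  sp <- corpus$spans
  sp$confidence <- runif(nrow(sp))
  cfg <- postprocess_config(confidence_threshold = 0.4)
  rec <- extract_affirmed(corpus$documents, sp, cfg, include_negated = TRUE)
  surviving <- sum(sp$label == "SYMPTOM" & sp$confidence >= 0.4)
  expect_equal(nrow(rec), surviving)
})

test_that("generator-known negation structure is recovered exactly", {
  corpus <- generate_corpus(generator_config(n_documents = 60L, seed = 91L,
                                             p_negation = 0.5))
  rec <- extract_affirmed(corpus$documents, corpus$spans, include_negated = TRUE)
  ## in the template grammar, a symptom is negated iff a cue directly precedes it
  gold_negated <- vapply(seq_len(nrow(rec)), function(k) {
    cues <- corpus$spans[corpus$spans$doc_id == rec$doc_id[k] &
                           corpus$spans$label == "NEGATION", ]
    any(cues$end == rec$start[k] - 1L)
  }, logical(1))
  expect_identical(rec$negated, gold_negated)
})
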