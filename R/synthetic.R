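#' Synthetic anamnesis generator configuration
#'
#' Defines the study conditions the generator emulates: short
#' emergency-department anamnesis narratives of 1-5 clauses containing
#' affirmed and negated symptom mentions, German-style compound pain words
#' ("Kopfschmerzen"), separate anatomy+pain constructions ("Schmerzen im
#' Rücken"), and slash-separated anatomy lists ("Rücken/Hüft und
#' Kopfschmerzen"), with gold spans marking every generated entity. The
#' embedded lexicon is deliberately small — enough to exercise compounds,
#' negation, and slash lists, with no claim of clinical realism.
#'
#' @param n_documents Number of narratives (default 150, the size of an
#'   annotated validation corpus in this setting).
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @param symptoms Named character vector: symptom surface -> its negation
#'   article ("Kein"/"Keine", for grammatical cue agreement).
#' @param anatomies Anatomy surfaces used for compounds and pain location.
#' @param slash_anatomies Anatomy stems for slash lists.
#' @param p_negation Probability a plain symptom clause is negated.
#' @param p_compound Probability a pain clause uses a compound word.
#' @param p_slash_list Probability a clause is a slash anatomy list.
#' @param template_weights Weights for the remaining clause kinds
#'   (`plain`, `pain`) after the slash draw.
#' @param clauses_range Min/max clauses per document.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_documents = 150L,
                             seed = NULL,
                             symptoms = c(
                               "Fieber" = "Kein", "Husten" = "Kein",
                               "Dyspnoe" = "Keine", "Übelkeit" = "Keine",
                               "Schwellung" = "Keine", "Rötung" = "Keine",
                               "Erbrechen" = "Kein", "Schwindel" = "Kein",
                               "Durchfall" = "Kein", "Obstipation" = "Keine",
                               "Erhöhte Temperatur" = "Keine"
                             ),
                             anatomies = c("Kopf", "Rücken", "Bauch",
                                           "Nacken", "Thorax"),
                             slash_anatomies = c("Rücken", "Hüft",
                                                 "Knie", "Schulter"),
                             p_negation = 0.3,
                             p_compound = 0.5,
                             p_slash_list = 0.1,
                             template_weights = c(plain = 0.6, pain = 0.4),
                             clauses_range = c(1L, 5L)) {
  for (nm in c("p_negation", "p_compound", "p_slash_list")) {
    check_fraction(get(nm), nm)
  }
  if (!length(symptoms) || !length(anatomies) || !length(slash_anatomies)) {
    stop_validation("lexicons must be non-empty")
  }
  structure(
    list(n_documents = as.integer(n_documents), seed = seed,
         symptoms = symptoms, anatomies = anatomies,
         slash_anatomies = slash_anatomies,
         p_negation = p_negation, p_compound = p_compound,
         p_slash_list = p_slash_list,
         template_weights = template_weights / sum(template_weights),
         clauses_range = as.integer(clauses_range)),
    class = "generator_config"
  )
}

pick <- function(x) x[[sample.int(length(x), 1L)]]

## one clause: text plus clause-relative gold spans
gen_clause <- function(cfg, conformant = TRUE) {
  span <- function(start, end, label) tibble(start = start, end = end, label = label)
  openers <- c("Seit Tagen", "Aktuell", "Zudem", "Patient berichtet", "Anamnestisch")

  kind <- if (runif(1) < cfg$p_slash_list) "slash" else {
    if (runif(1) < cfg$template_weights[["plain"]]) "plain" else "pain"
  }

  if (kind == "plain") {
    sym <- pick(names(cfg$symptoms))
    if (runif(1) < cfg$p_negation) {
      cue <- cfg$symptoms[[sym]]
      text <- paste0(cue, " ", sym, ".")
      spans <- bind_rows(
        span(0L, nchar(cue), "NEGATION"),
        span(nchar(cue) + 1L, nchar(cue) + 1L + nchar(sym), "SYMPTOM")
      )
    } else {
      op <- pick(openers)
      text <- paste0(op, " ", sym, ".")
      spans <- span(nchar(op) + 1L, nchar(op) + 1L + nchar(sym), "SYMPTOM")
    }
  } else if (kind == "pain") {
    ana <- pick(cfg$anatomies)
    if (runif(1) < cfg$p_compound) {
      compound <- paste0(ana, "schmerzen")
      text <- paste0(compound, " seit gestern.")
      spans <- if (conformant) {
        span(0L, nchar(compound), "SYMPTOM")
      } else {
        ## guideline violation: compound split into anatomy + symptom
        bind_rows(span(0L, nchar(ana), "ANATOMY"),
                  span(nchar(ana), nchar(compound), "SYMPTOM"))
      }
    } else {
      text <- paste0("Schmerzen im ", ana, ".")
      spans <- bind_rows(
        span(0L, 9L, "SYMPTOM"),
        span(13L, 13L + nchar(ana), "ANATOMY")
      )
    }
  } else {
    pair <- sample(cfg$slash_anatomies, 2L)
    ana <- pick(cfg$anatomies)
    compound <- paste0(ana, "schmerzen")
    text <- paste0(pair[1], "/", pair[2], " und ", compound, " seit heute.")
    a1 <- nchar(pair[1]); a2 <- nchar(pair[2])
    spans <- if (conformant) {
      bind_rows(
        span(0L, a1, "ANATOMY"),
        span(a1 + 1L, a1 + 1L + a2, "ANATOMY"),
        span(a1 + a2 + 6L, a1 + a2 + 6L + nchar(compound), "SYMPTOM")
      )
    } else {
      ## guideline violation: slash list merged into one anatomy span
      bind_rows(
        span(0L, a1 + 1L + a2, "ANATOMY"),
        span(a1 + a2 + 6L, a1 + a2 + 6L + nchar(compound), "SYMPTOM")
      )
    }
  }
  list(text = text, spans = spans)
}

#' Generate a gold-annotated synthetic corpus
#'
#' Seed-deterministic: the same configuration (including seed) yields a
#' byte-identical corpus. Gold spans exactly mark each generated entity and,
#' in conformant mode (the default), always pass [lint_guidelines()].
#'
#' @param config A [generator_config()].
#' @param conformant Generate guideline-conformant gold annotations
#'   (compounds in a single span, slash lists split). `FALSE` produces the
#'   corresponding guideline violations, for exercising the linter.
#' @return A `doccano_corpus` list: `documents`, `spans` (annotator
#'   `"gold"`), `unknown_labels` (empty).
#' @export
generate_corpus <- function(config = generator_config(), conformant = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  with_preserved_seed(config$seed, {
    docs <- vector("list", config$n_documents)
    span_rows <- vector("list", config$n_documents)
    width <- max(4L, nchar(as.character(config$n_documents)))
    for (i in seq_len(config$n_documents)) {
      doc_id <- sprintf(paste0("doc_%0", width, "d"), i)
      n_clauses <- sample(seq(config$clauses_range[1], config$clauses_range[2]), 1L)
      cursor <- 0L
      parts <- character(n_clauses)
      spans <- vector("list", n_clauses)
      for (k in seq_len(n_clauses)) {
        cl <- gen_clause(config, conformant)
        parts[k] <- cl$text
        cl$spans$start <- cl$spans$start + cursor
        cl$spans$end <- cl$spans$end + cursor
        spans[[k]] <- cl$spans
        cursor <- cursor + nchar(cl$text) + 1L  # single-space clause join
      }
      docs[[i]] <- list(
        doc_id = doc_id, text = paste(parts, collapse = " "),
        metadata = list(sex = pick(c("F", "M")),
                        age_group = pick(c("18-39", "40-64", "65+")))
      )
      sp <- bind_rows(spans)
      sp$doc_id <- doc_id
      span_rows[[i]] <- sp
    }
    documents <- clin_corpus(
      doc_id = vapply(docs, `[[`, character(1), "doc_id"),
      text = vapply(docs, `[[`, character(1), "text"),
      metadata = lapply(docs, `[[`, "metadata")
    )
    spans <- as_span_tbl(bind_rows(span_rows))
    spans$annotator <- "gold"
    spans <- materialize_surface(spans, documents)
    structure(
      list(documents = documents, spans = spans, unknown_labels = clin_spans()),
      class = "doccano_corpus"
    )
  })
}

#' The lexicon implied by a generator configuration
#'
#' Every surface the generator can emit, with its label: symptoms, compound
#' pain words, the bare pain term, anatomies (including slash stems), and
#' negation cues. A [lexicon_backend()] built from this lexicon is perfect
#' on corpora from the same configuration.
#'
#' @param config A [generator_config()].
#' @return A lexicon tibble (`label`, `surface`).
#' @export
generator_lexicon <- function(config) {
  bind_rows(
    tibble(label = "SYMPTOM", surface = names(config$symptoms)),
    tibble(label = "SYMPTOM", surface = paste0(config$anatomies, "schmerzen")),
    tibble(label = "SYMPTOM", surface = "Schmerzen"),
    tibble(label = "ANATOMY", surface = unique(c(config$anatomies, config$slash_anatomies))),
    tibble(label = "NEGATION", surface = unique(unname(config$symptoms)))
  )
}

#' Corruption model configuration
#'
#' Controlled degradation of a gold annotation set into synthetic
#' "predictions" with analytically known expected metrics. Each gold span is
#' independently dropped with probability `p_miss`, else boundary-shifted
#' with probability `p_shift` (one token edge by default, so shifted spans
#' stay token-aligned and still overlap the original), else label-flipped
#' with probability `p_type` (boundaries kept), else copied exactly.
#' Spurious spans (random token-aligned intervals with random labels, never
#' overlapping gold) are added at an expected rate of `p_spurious` per
#' document — keeping the closed forms in [expected_metrics()] exact.
#'
#' @param p_miss,p_shift,p_type Branch probabilities; their sum must be
#'   at most 1.
#' @param p_spurious Expected spurious spans per document (Poisson rate).
#' @param shift_mode `"token"` (default) or `"character"`.
#' @param seed Integer seed for reproducible corruption.
#' @return A list of class `corruption_config`.
#' @export
corruption_config <- function(p_miss = 0, p_shift = 0, p_type = 0,
                              p_spurious = 0, shift_mode = c("token", "character"),
                              seed = NULL) {
  for (nm in c("p_miss", "p_shift", "p_type")) check_fraction(get(nm), nm)
  if (p_miss + p_shift + p_type > 1 + 1e-12) {
    stop_validation("p_miss + p_shift + p_type must be <= 1")
  }
  if (p_spurious < 0) stop_validation("p_spurious must be >= 0")
  structure(
    list(p_miss = p_miss, p_shift = p_shift, p_type = p_type,
         p_spurious = p_spurious, shift_mode = match.arg(shift_mode),
         seed = seed),
    class = "corruption_config"
  )
}

shift_span <- function(start, end, edges, n_char, mode) {
  if (mode == "token") {
    left_out <- edges[edges < start]
    left_in <- edges[edges > start & edges < end]
    right_in <- edges[edges > start & edges < end]
    right_out <- edges[edges > end]
    ops <- list()
    if (length(left_out)) ops <- c(ops, list(c(max(left_out), end)))    # extend left
    if (length(right_out)) ops <- c(ops, list(c(start, min(right_out)))) # extend right
    if (length(left_in)) ops <- c(ops, list(c(min(left_in), end)))       # shrink left
    if (length(right_in)) ops <- c(ops, list(c(start, max(right_in))))   # shrink right
  } else {
    ops <- list()
    if (start > 0L) ops <- c(ops, list(c(start - 1L, end)))
    if (end < n_char) ops <- c(ops, list(c(start, end + 1L)))
    if (end - start > 1L) ops <- c(ops, list(c(start + 1L, end), c(start, end - 1L)))
  }
  if (!length(ops)) return(c(start, end))  # no valid perturbation; keep
  unlist(pick(ops))
}

#' Corrupt a gold annotation set into synthetic predictions
#'
#' @param gold A `doccano_corpus` or span table of gold annotations.
#' @param documents Corpus tibble (taken from `gold` when it is a
#'   `doccano_corpus`).
#' @param config A [corruption_config()].
#' @return A span table of synthetic predictions (annotator `"corrupted"`).
#' @export
corrupt_annotations <- function(gold, documents = NULL, config = corruption_config()) {
  stopifnot(inherits(config, "corruption_config"))
  if (inherits(gold, "doccano_corpus")) {
    documents <- documents %||% gold$documents
    gold <- gold$spans
  }
  gold <- as_span_tbl(gold)
  if (is.null(documents)) stop_validation("`documents` is required")

  with_preserved_seed(config$seed, {
    edge_cache <- lapply(documents$text, function(tx) {
      toks <- tokenize(tx)
      list(edges = sort(unique(c(toks$start, toks$end))), toks = toks,
           n_char = nchar(tx))
    })
    names(edge_cache) <- documents$doc_id

    rows <- list()
    for (k in seq_len(nrow(gold))) {
      u <- runif(1)
      if (u < config$p_miss) next
      start <- gold$start[k]; end <- gold$end[k]; label <- gold$label[k]
      info <- edge_cache[[gold$doc_id[k]]]
      if (u < config$p_miss + config$p_shift) {
        se <- shift_span(start, end, info$edges, info$n_char, config$shift_mode)
        start <- se[1]; end <- se[2]
      } else if (u < config$p_miss + config$p_shift + config$p_type) {
        label <- pick(setdiff(ENTITY_LABELS, label))
      }
      rows[[length(rows) + 1L]] <- tibble(
        doc_id = gold$doc_id[k], start = as.integer(start), end = as.integer(end),
        label = label
      )
    }

    ## spurious spans: token-aligned, never overlapping gold
    if (config$p_spurious > 0) {
      for (d in documents$doc_id) {
        n_spur <- rpois(1, config$p_spurious)
        if (n_spur == 0L) next
        info <- edge_cache[[d]]
        gsel <- gold[gold$doc_id == d, , drop = FALSE]
        placed <- list()
        for (s in seq_len(n_spur)) {
          for (attempt in 1:20) {
            t0 <- sample.int(nrow(info$toks), 1L)
            t1 <- min(t0 + sample.int(2L, 1L) - 1L, nrow(info$toks))
            cand <- c(info$toks$start[t0], info$toks$end[t1])
            all_sp <- bind_rows(placed)
            clash <- any(gsel$start < cand[2] & gsel$end > cand[1]) ||
              (length(placed) && any(all_sp$start < cand[2] & all_sp$end > cand[1]))
            if (!clash) {
              placed[[length(placed) + 1L]] <- tibble(
                doc_id = d, start = cand[1], end = cand[2],
                label = pick(ENTITY_LABELS)
              )
              break
            }
          }
        }
        rows <- c(rows, placed)
      }
    }

    pred <- if (length(rows)) as_span_tbl(bind_rows(rows)) else clin_spans()
    pred <- pred[!duplicated(pred[c("doc_id", "start", "end", "label")]), , drop = FALSE]
    pred$annotator <- "corrupted"
    materialize_surface(pred, documents)
  })
}

#' Closed-form expected metrics under the corruption model
#'
#' For the pooled ALL-labels scope. With miss rate `m`, shift rate `s`,
#' type-flip rate `t` (mutually exclusive branches: shifted spans keep their
#' label, flipped spans keep exact boundaries) and spurious rate `lambda`
#' per document, the expected recall credit per gold span is
#'
#' * STRICT: `(1-m)(1-s)(1-t)` — only exact copies;
#' * EXACT: `(1-m)(1-s)` — label ignored, so flips still count;
#' * PARTIAL: `(1-m)((1-s) + w*s)` with partial credit `w` — a shifted span
#'   still overlaps its source and scores `w`;
#' * TYPE: `(1-m)(s + (1-s)(1-t))` — shifts keep the label and overlap.
#'
#' Expected precision divides the same credit by the expected prediction
#' count per gold span, `(1-m) + D*lambda/N`. Standard errors come from the
#' per-span credit variance (recall), a delta-method ratio variance
#' (precision, accounting for the random denominator), and first-order
#' propagation through the harmonic mean (F1).
#'
#' @param config A [corruption_config()].
#' @param n_gold Number of gold spans in the corpus.
#' @param n_documents Number of documents (spurious spans scale with it).
#' @param partial_credit Credit for PAR pairs (default 0.5).
#' @return A tibble: `granularity`, `precision`, `recall`, `f1`, and their
#'   standard errors `se_precision`, `se_recall`, `se_f1`.
#' @export
expected_metrics <- function(config, n_gold, n_documents,
                             partial_credit = 0.5) {
  stopifnot(inherits(config, "corruption_config"))
  m <- config$p_miss; s <- config$p_shift; t <- config$p_type
  w <- check_fraction(partial_credit, "partial_credit")
  N <- n_gold; D <- n_documents; lam <- config$p_spurious
  q <- 1 - m                      # span survives
  EM <- N * q + D * lam           # expected prediction count
  VM <- N * q * m + D * lam       # Var(M): binomial survivals + Poisson spurious

  per_gran <- function(full, half) {
    ## credit X in {1 (w.p. full), w (w.p. half), 0}
    mu <- full + w * half
    ex2 <- full + w^2 * half
    v <- ex2 - mu^2
    recall <- mu
    se_recall <- sqrt(v / N)
    ES <- N * mu
    precision <- if (EM > 0) ES / EM else 0
    ## delta method for S/M with Cov(S, M) = N * mu * m (credit implies survival)
    se_precision <- if (EM > 0 && ES > 0) {
      covSM <- N * mu * m
      precision * sqrt(max(0, N * v / ES^2 + VM / EM^2 - 2 * covSM / (ES * EM)))
    } else if (EM > 0) {
      sqrt(N * v) / EM
    } else {
      0
    }
    f1 <- f1_score(precision, recall)
    se_f1 <- if (precision + recall > 0) {
      dP <- 2 * recall^2 / (precision + recall)^2
      dR <- 2 * precision^2 / (precision + recall)^2
      covPR <- if (EM > 0) (N * v) / (N * EM) else 0
      sqrt(max(0, (dP * se_precision)^2 + (dR * se_recall)^2 +
                 2 * dP * dR * covPR))
    } else {
      0
    }
    tibble(precision = precision, recall = recall, f1 = f1,
           se_precision = se_precision, se_recall = se_recall, se_f1 = se_f1)
  }

  out <- bind_rows(
    mutate(per_gran(full = q * (1 - s) * (1 - t), half = 0), granularity = "STRICT"),
    mutate(per_gran(full = q * (1 - s), half = 0), granularity = "EXACT"),
    mutate(per_gran(full = q * (1 - s), half = q * s), granularity = "PARTIAL"),
    mutate(per_gran(full = q * (s + (1 - s) * (1 - t)), half = 0), granularity = "TYPE")
  )
  out[, c("granularity", "precision", "recall", "f1",
          "se_precision", "se_recall", "se_f1")]
}
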