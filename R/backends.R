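#' Wrap a prediction function as an NER backend
#'
#' The uniform backend contract: any object that can map one document to a
#' span table. Human annotations, rule/lexicon scanners, fine-tuned token
#' classifiers, and prompted generative models all fit behind the same
#' interface, so the evaluation machinery never needs to know which is
#' which. A token-classifier adapter is simply a `ner_backend()` around the
#' user's own inference function; no model weights ship with the package.
#'
#' @param name Backend name.
#' @param predict `function(doc_id, text)` returning a span table.
#' @param emits_confidence,emits_offsets Capability flags.
#' @return An object of class `ner_backend`.
#' @export
ner_backend <- function(name, predict, emits_confidence = FALSE,
                        emits_offsets = TRUE) {
  stopifnot(is.function(predict))
  structure(
    list(name = name, predict = predict,
         emits_confidence = isTRUE(emits_confidence),
         emits_offsets = isTRUE(emits_offsets)),
    class = "ner_backend"
  )
}

#' @export
print.ner_backend <- function(x, ...) {
  cat(sprintf("<ner_backend> %s (confidence: %s, offsets: %s)\n",
              x$name, x$emits_confidence, x$emits_offsets))
  invisible(x)
}

#' Run a backend over a corpus
#'
#' Applies the backend to every document and validates that the emitted
#' spans satisfy the span invariants against the input text.
#'
#' @param backend A `ner_backend`.
#' @param documents Corpus tibble.
#' @return A span table covering the corpus.
#' @export
predict_spans <- function(backend, documents) {
  stopifnot(inherits(backend, "ner_backend"))
  out <- lapply(seq_len(nrow(documents)), function(i) {
    as_span_tbl(backend$predict(documents$doc_id[i], documents$text[i]))
  })
  spans <- bind_rows(out)
  if (!nrow(spans)) return(clin_spans())
  bad <- validate_spans(documents, spans)
  if (nrow(bad)) {
    stop_validation(sprintf("backend '%s' emitted invalid spans (%s)",
                            backend$name, paste(unique(bad$problem), collapse = "; ")))
  }
  spans
}

#' Read a lexicon file
#'
#' @param x Path to a two-column TSV (`label<TAB>surface`, `#` comments
#'   allowed), or a named list `label -> character vector of surfaces`, or a
#'   data frame with columns `label` and `surface`.
#' @return A tibble with columns `label` and `surface`.
#' @export
read_lexicon <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_io(sprintf("no such lexicon file: %s", x))
    x <- read.delim(x, header = FALSE, comment.char = "#",
                    col.names = c("label", "surface"),
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- tibble(label = rep(names(x), lengths(x)),
                surface = as.character(unlist(x, use.names = FALSE)))
  }
  if (!nrow(as_tibble(x))) {
    return(tibble(label = character(), surface = character()))
  }
  as_tibble(x)[, c("label", "surface")]
}

## all case-insensitive, word-bounded occurrences of `surface` in `text`
find_occurrences <- function(surface, text) {
  m <- gregexpr(tolower(surface), tolower(text), fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  start <- as.integer(m) - 1L
  end <- start + nchar(surface)
  ## reject matches embedded in a longer word
  keep <- vapply(seq_along(start), function(k) {
    before <- if (start[k] > 0L) slice_text(text, start[k] - 1L, start[k]) else ""
    after <- if (end[k] < nchar(text)) slice_text(text, end[k], end[k] + 1L) else ""
    !grepl("\\p{L}", before, perl = TRUE) && !grepl("^\\p{L}", after, perl = TRUE)
  }, logical(1))
  start[keep]
}

#' Deterministic lexicon/rule backend
#'
#' The reference backend: a longest-match, case-insensitive, word-bounded
#' scan of the text against a lexicon of labeled surfaces, emitting
#' non-overlapping spans (leftmost-longest wins). Confidence is 1.0 for an
#' exact case match and 0.8 otherwise. On a corpus generated from the same
#' lexicon this backend is perfect by construction, which makes it the
#' end-to-end smoke test for the whole evaluation stack.
#'
#' @param lexicon See [read_lexicon()].
#' @param name Backend name.
#' @return A `ner_backend`.
#' @export
lexicon_backend <- function(lexicon, name = "lexicon") {
  lexicon <- read_lexicon(lexicon)
  predict <- function(doc_id, text) {
    if (!nrow(lexicon)) return(clin_spans())
    cands <- list()
    for (k in seq_len(nrow(lexicon))) {
      starts <- find_occurrences(lexicon$surface[k], text)
      for (s in starts) {
        e <- s + nchar(lexicon$surface[k])
        cands[[length(cands) + 1L]] <- list(
          start = s, end = e, label = lexicon$label[k],
          exact_case = slice_text(text, s, e) == lexicon$surface[k]
        )
      }
    }
    if (!length(cands)) return(clin_spans())
    start <- vapply(cands, `[[`, numeric(1), "start")
    end <- vapply(cands, `[[`, numeric(1), "end")
    ord <- order(start, -(end - start))
    sel <- logical(length(ord))
    last_end <- -1L
    for (k in ord) {
      if (start[k] >= last_end) {
        sel[k] <- TRUE
        last_end <- end[k]
      }
    }
    keep <- which(sel)
    clin_spans(
      doc_id = doc_id,
      start = start[keep], end = end[keep],
      label = vapply(cands[keep], `[[`, character(1), "label"),
      surface = slice_text(text, start[keep], end[keep]),
      confidence = ifelse(vapply(cands[keep], `[[`, logical(1), "exact_case"), 1, 0.8)
    )
  }
  ner_backend(name, predict, emits_confidence = TRUE)
}

#' Zero-shot prompt schema (three parts)
#'
#' The prompt given to a generative model has three parts: entity
#' definitions, worked examples with solutions, and a fixed closing
#' instruction asking for reasoning plus a machine-readable Python-style
#' list of the found entities. All three parts must be non-empty.
#'
#' @param part1_definitions Text defining the three entity types.
#' @param part2_examples List of examples, each a list with `narrative` and
#'   `entities` (character vector of solved entities).
#' @param part3_instruction The fixed instruction text.
#' @return A list of class `prompt_schema`.
#' @export
prompt_schema <- function(part1_definitions, part2_examples, part3_instruction) {
  if (!nzchar(trimws(part1_definitions %||% ""))) {
    stop_validation("part 1 (entity definitions) must be non-empty")
  }
  if (!length(part2_examples)) {
    stop_validation("part 2 (worked examples) must be non-empty")
  }
  if (!nzchar(trimws(part3_instruction %||% ""))) {
    stop_validation("part 3 (instruction) must be non-empty")
  }
  structure(
    list(part1_definitions = part1_definitions,
         part2_examples = part2_examples,
         part3_instruction = part3_instruction),
    class = "prompt_schema"
  )
}

#' The shipped default prompt schema
#'
#' Read from `inst/extdata/prompt_schema_de.json`: German entity definitions
#' for symptom / anatomical position / negation, two worked examples, and
#' the fixed German closing instruction (an English alternative is available
#' with `language = "en"` for the instruction part).
#'
#' @param language `"de"` (default) or `"en"` for the part-3 instruction.
#' @return A `prompt_schema`.
#' @export
default_prompt_schema <- function(language = c("de", "en")) {
  language <- match.arg(language)
  raw <- jsonlite::fromJSON(
    system.file("extdata", "prompt_schema_de.json", package = "clinspan"),
    simplifyVector = FALSE
  )
  prompt_schema(
    part1_definitions = raw$part1_definitions,
    part2_examples = raw$part2_examples,
    part3_instruction = raw$part3_instruction[[language]]
  )
}

#' Build the zero-shot prompt for one narrative
#'
#' Pure function: a deterministic concatenation of the entity definitions,
#' the worked examples, the narrative, and the closing instruction —
#' byte-identical output for identical inputs.
#'
#' @param schema A [prompt_schema()].
#' @param narrative Non-empty narrative text.
#' @return The prompt string.
#' @export
build_prompt <- function(schema, narrative) {
  stopifnot(inherits(schema, "prompt_schema"))
  if (is.null(narrative) || is.na(narrative) || !nzchar(trimws(narrative))) {
    stop_validation("narrative must be non-empty")
  }
  examples <- vapply(schema$part2_examples, function(ex) {
    sprintf("Text: %s\nEntities: [%s]", ex$narrative,
            paste(sprintf("'%s'", unlist(ex$entities)), collapse = ", "))
  }, character(1))
  paste(
    schema$part1_definitions,
    paste(examples, collapse = "\n\n"),
    sprintf("Text: %s", narrative),
    schema$part3_instruction,
    sep = "\n\n"
  )
}

#' Parse the entity list out of a model response
#'
#' Generative models are instructed to end their answer with a Python-style
#' list. The parser extracts the last bracketed list literal in the
#' response (free-text reasoning before it is discarded), reads its
#' elements as quoted strings, and optionally splits `"surface:LABEL"`
#' pairs into a surface and a label guess. A response with no parseable
#' list yields zero rows with the `parse_failed` attribute set — failures
#' are data, not errors.
#'
#' @param response Model response text.
#' @return A tibble with columns `entity` and `label` (NA when no label was
#'   given); attribute `parse_failed` is `TRUE` when no list was found.
#' @export
parse_entity_list <- function(response) {
  empty <- tibble(entity = character(), label = character())
  if (is.null(response) || is.na(response) || !nzchar(response)) {
    return(structure(empty, parse_failed = TRUE))
  }
  lists <- regmatches(response, gregexpr("\\[[^][]*\\]", response))[[1]]
  if (!length(lists)) return(structure(empty, parse_failed = TRUE))
  last <- lists[length(lists)]
  items <- regmatches(last, gregexpr("'[^']*'|\"[^\"]*\"", last))[[1]]
  if (!length(items)) return(structure(empty, parse_failed = TRUE))
  items <- substr(items, 2L, nchar(items) - 1L)
  entity <- items
  label <- rep(NA_character_, length(items))
  pair <- grepl(":", items, fixed = TRUE)
  if (any(pair)) {
    guess <- toupper(trimws(sub("^.*:", "", items[pair])))
    ok <- guess %in% ENTITY_LABELS
    label[pair][ok] <- guess[ok]
    entity[pair][ok] <- trimws(sub(":[^:]*$", "", items[pair][ok]))
  }
  structure(tibble(entity = entity, label = label), parse_failed = FALSE)
}

#' Ground entity strings back to character offsets
#'
#' Generative output has no offsets; evaluation needs spans. Each entity
#' string is located by a case-insensitive search of the narrative and every
#' non-overlapping occurrence becomes a span. Strings absent from the text
#' are reported as ungrounded; by default they are excluded (and available
#' in the `ungrounded` attribute) rather than counted as spurious
#' predictions, because an unlocatable string has no defensible boundary.
#'
#' @param entities Tibble from [parse_entity_list()] (or a character vector
#'   of entity strings).
#' @param doc_id,text The target document.
#' @param default_label Label assigned when the model gave none.
#' @param spurious_ungrounded Reserved flag; ungrounded strings never
#'   produce spans (they have no offsets), this only controls whether they
#'   are recorded in the attribute (`FALSE`, default) or also warned about.
#' @return A span table; attribute `ungrounded` holds the unlocatable
#'   strings.
#' @export
ground_entities <- function(entities, doc_id, text, default_label = "SYMPTOM",
                            spurious_ungrounded = FALSE) {
  if (is.character(entities)) {
    entities <- tibble(entity = entities, label = NA_character_)
  }
  rows <- list()
  ungrounded <- character()
  for (k in seq_len(nrow(entities))) {
    surf <- entities$entity[k]
    if (!nzchar(surf)) next
    starts <- find_all_substrings(surf, text)
    if (!length(starts)) {
      ungrounded <- c(ungrounded, surf)
      next
    }
    lab <- entities$label[k]
    if (is.na(lab)) lab <- default_label
    rows[[length(rows) + 1L]] <- clin_spans(
      doc_id = doc_id, start = starts, end = starts + nchar(surf),
      label = lab, surface = slice_text(text, starts, starts + nchar(surf))
    )
  }
  spans <- if (length(rows)) bind_rows(rows) else clin_spans()
  spans <- spans[!duplicated(spans[c("start", "end", "label")]), , drop = FALSE]
  if (length(ungrounded) && isTRUE(spurious_ungrounded)) {
    warn(sprintf("ungrounded entity string(s): %s",
                 paste(shQuote(ungrounded), collapse = ", ")))
  }
  attr(spans, "ungrounded") <- ungrounded
  spans
}

## all case-insensitive, non-overlapping occurrences (no word-boundary
## requirement: the model's string is taken at face value)
find_all_substrings <- function(surface, text) {
  m <- gregexpr(tolower(surface), tolower(text), fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  as.integer(m) - 1L
}

#' Prompted generative backend
#'
#' Adapter honoring the backend contract for any local text-completion
#' service: the caller supplies `complete`, a `function(prompt) -> response
#' text` (for instance a thin wrapper around a local HTTP completion
#' endpoint, keeping all text on-premises). The adapter builds the prompt
#' from the schema, parses the trailing entity list out of the response, and
#' grounds the entities to character offsets.
#'
#' @param complete `function(prompt)` returning the model's response text.
#' @param schema A [prompt_schema()].
#' @param name Backend name.
#' @param default_label Label for entities the model did not label.
#' @return A `ner_backend`.
#' @export
llm_backend <- function(complete, schema = default_prompt_schema(),
                        name = "llm", default_label = "SYMPTOM") {
  stopifnot(is.function(complete))
  predict <- function(doc_id, text) {
    response <- complete(build_prompt(schema, text))
    ground_entities(parse_entity_list(response), doc_id, text,
                    default_label = default_label)
  }
  ner_backend(name, predict, emits_confidence = FALSE)
}
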