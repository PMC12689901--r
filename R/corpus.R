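#' Construct a corpus of clinical narratives
#'
#' A corpus is a tibble with one row per document: an opaque `doc_id`, the
#' UTF-8 narrative `text`, and an optional `metadata` list-column (free-form
#' per-document fields such as sex, age group, or a diagnosis code).
#'
#' @param doc_id Character vector of unique document identifiers.
#' @param text Character vector of non-empty narratives, same length.
#' @param metadata Optional list of per-document metadata (named lists).
#' @return A tibble with columns `doc_id`, `text`, and `metadata`.
#' @export
clin_corpus <- function(doc_id, text, metadata = NULL) {
  doc_id <- as.character(doc_id)
  text <- as.character(text)
  if (length(doc_id) != length(text)) {
    stop_validation("`doc_id` and `text` must have the same length")
  }
  if (anyDuplicated(doc_id)) {
    stop_validation(sprintf("duplicate doc_id: %s",
                            paste(unique(doc_id[duplicated(doc_id)]), collapse = ", ")))
  }
  if (any(!nzchar(text))) {
    stop_validation(sprintf("empty text for doc_id: %s",
                            paste(doc_id[!nzchar(text)], collapse = ", ")))
  }
  if (is.null(metadata)) metadata <- rep(list(NULL), length(doc_id))
  tibble(doc_id = doc_id, text = text, metadata = metadata)
}

#' Construct a span table
#'
#' Spans are labeled character intervals into a parent document: 0-based,
#' half-open `[start, end)` offsets (the Doccano convention), one of the
#' three entity labels, the materialized `surface` slice, and an optional
#' `confidence` in `[0, 1]` (NA when the backend emits none). An annotation
#' set is a span table plus an `annotator` column.
#'
#' @param doc_id,start,end,label Parallel vectors defining the spans.
#' @param surface Optional surface strings; materialize with
#'   [materialize_surface()] when a corpus is available.
#' @param confidence Optional numeric confidences in `[0, 1]`.
#' @param annotator Optional annotator identifier.
#' @return A tibble with columns `doc_id`, `start`, `end`, `label`,
#'   `surface`, `confidence`, `annotator`.
#' @export
clin_spans <- function(doc_id = character(), start = integer(), end = integer(),
                       label = character(), surface = NA_character_,
                       confidence = NA_real_, annotator = NA_character_) {
  n <- length(start)
  tibble(
    doc_id = rep_len(as.character(doc_id), n),
    start = as.integer(start),
    end = as.integer(end),
    label = rep_len(as.character(label), n),
    surface = rep_len(as.character(surface), n),
    confidence = rep_len(as.numeric(confidence), n),
    annotator = rep_len(as.character(annotator), n)
  )
}

## ensure a span table carries all expected columns
as_span_tbl <- function(spans) {
  spans <- as_tibble(spans)
  if (!nrow(spans) && !all(c("doc_id", "start", "end", "label") %in% names(spans))) {
    return(clin_spans())
  }
  for (col in c("surface", "annotator")) {
    if (is.null(spans[[col]])) spans[[col]] <- NA_character_
  }
  if (is.null(spans[["confidence"]])) spans$confidence <- NA_real_
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  spans
}

#' Fill span surfaces from the corpus text
#'
#' @param spans A span table.
#' @param documents A corpus tibble.
#' @return `spans` with `surface` set to `text[start:end]`.
#' @export
materialize_surface <- function(spans, documents) {
  spans <- as_span_tbl(spans)
  idx <- match(spans$doc_id, documents$doc_id)
  if (anyNA(idx) && nrow(spans)) {
    stop_validation(sprintf("spans reference unknown doc_id: %s",
                            paste(unique(spans$doc_id[is.na(idx)]), collapse = ", ")))
  }
  spans$surface <- slice_text(documents$text[idx], spans$start, spans$end)
  spans
}

#' Read a Doccano-style JSONL corpus
#'
#' One JSON object per line with a `text` field and a `label` (or
#' `entities`) field holding `[start, end, label]` triples; character
#' offsets, 0-based half-open. Surfaces are materialized from the text.
#' Spans with a label outside the three-label scheme are not silently
#' dropped: they are collected into `$unknown_labels` and excluded from
#' `$spans`.
#'
#' @param input Path to a JSONL file, or a character vector of JSONL lines.
#' @param annotator Optional annotator id recorded on every span.
#' @return A list of class `doccano_corpus` with elements `documents`
#'   (corpus tibble), `spans` (span table), and `unknown_labels` (span table
#'   of rows whose label is outside [entity_labels()]).
#' @export
read_doccano <- function(input, annotator = NA_character_) {
  lines <- if (length(input) == 1L && !grepl("[{\n]", input)) {
    if (!file.exists(input)) stop_io(sprintf("no such file: %s", input))
    readLines(input, encoding = "UTF-8", warn = FALSE)
  } else {
    input
  }
  lines <- lines[nzchar(trimws(lines))]

  docs <- vector("list", length(lines))
  span_rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop_io(sprintf("line %d: malformed JSON (%s)", i, conditionMessage(e)))
      }
    )
    if (is.null(obj$text)) stop_io(sprintf("line %d: missing `text` field", i))
    text <- as.character(obj$text)
    doc_id <- as.character(obj$id %||% i)
    meta <- obj$meta %||% NULL
    labels <- obj$label %||% obj$entities %||% list()

    n_char <- nchar(text)
    triples <- lapply(seq_along(labels), function(k) {
      tr <- labels[[k]]
      if (length(tr) != 3L) {
        stop_io(sprintf("line %d (doc %s): label entry %d is not a [start, end, label] triple",
                        i, doc_id, k))
      }
      s <- as.integer(tr[[1]]); e <- as.integer(tr[[2]]); lab <- as.character(tr[[3]])
      if (is.na(s) || is.na(e) || s < 0L || e > n_char || s >= e) {
        stop_validation(sprintf(
          "line %d (doc %s): span [%s, %s) out of bounds for a %d-character text",
          i, doc_id, tr[[1]], tr[[2]], n_char))
      }
      list(start = s, end = e, label = lab)
    })
    docs[[i]] <- list(doc_id = doc_id, text = text, metadata = meta)
    if (length(triples)) {
      span_rows[[i]] <- tibble(
        doc_id = doc_id,
        start = vapply(triples, `[[`, integer(1), "start"),
        end = vapply(triples, `[[`, integer(1), "end"),
        label = vapply(triples, `[[`, character(1), "label")
      )
    }
  }

  documents <- clin_corpus(
    doc_id = vapply(docs, `[[`, character(1), "doc_id"),
    text = vapply(docs, `[[`, character(1), "text"),
    metadata = lapply(docs, `[[`, "metadata")
  )
  spans <- if (length(span_rows)) bind_rows(span_rows) else clin_spans()
  spans <- as_span_tbl(spans)
  spans$annotator <- annotator
  spans <- materialize_surface(spans, documents)

  unknown <- spans[!spans$label %in% ENTITY_LABELS, , drop = FALSE]
  spans <- spans[spans$label %in% ENTITY_LABELS, , drop = FALSE]
  if (nrow(unknown)) {
    warn(sprintf("%d span(s) with unknown label (%s) excluded; see $unknown_labels",
                 nrow(unknown), paste(unique(unknown$label), collapse = ", ")))
  }
  structure(
    list(documents = documents, spans = spans, unknown_labels = unknown),
    class = "doccano_corpus"
  )
}

#' @export
print.doccano_corpus <- function(x, ...) {
  cat(sprintf("<doccano_corpus> %d document(s), %d span(s)",
              nrow(x$documents), nrow(x$spans)))
  if (nrow(x$unknown_labels)) {
    cat(sprintf(", %d with unknown label", nrow(x$unknown_labels)))
  }
  cat("\n")
  if (nrow(x$spans)) {
    tab <- table(x$spans$label)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Write a corpus and its spans as Doccano-style JSONL
#'
#' Emits the `label` field name (triples of `[start, end, label]`), one
#' document per line. Reading the result back reproduces the same
#' `(text, start, end, label)` tuples.
#'
#' @param documents Corpus tibble, or a `doccano_corpus`.
#' @param spans Span table (ignored when `documents` is a `doccano_corpus`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_doccano <- function(documents, spans = NULL, path) {
  if (inherits(documents, "doccano_corpus")) {
    spans <- documents$spans
    documents <- documents$documents
  }
  spans <- as_span_tbl(spans %||% clin_spans())
  by_doc <- split(spans, factor(spans$doc_id, levels = documents$doc_id))
  lines <- vapply(seq_len(nrow(documents)), function(i) {
    ss <- by_doc[[documents$doc_id[i]]]
    labs <- if (!is.null(ss) && nrow(ss)) {
      lapply(seq_len(nrow(ss)), function(k) list(ss$start[k], ss$end[k], ss$label[k]))
    } else {
      list()
    }
    jsonlite::toJSON(
      list(id = documents$doc_id[i], text = documents$text[i], label = labs),
      auto_unbox = TRUE, digits = NA
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Validate spans against their documents
#'
#' Checks the span invariants: known `doc_id`, `0 <= start < end <=
#' nchar(text)`, surface equal to the text slice, confidence in `[0, 1]`
#' when present, and no duplicate `(start, end, label)` triples within one
#' document and annotator. Violations are returned as data, not raised.
#'
#' @param documents Corpus tibble.
#' @param spans Span table.
#' @return A tibble of violations with columns `doc_id`, `start`, `end`,
#'   `label`, `problem`; zero rows iff all invariants hold.
#' @export
validate_spans <- function(documents, spans) {
  spans <- as_span_tbl(spans)
  out <- list()
  note <- function(rows, problem) {
    if (any(rows)) {
      out[[length(out) + 1L]] <<- tibble(
        doc_id = spans$doc_id[rows], start = spans$start[rows],
        end = spans$end[rows], label = spans$label[rows], problem = problem
      )
    }
  }
  idx <- match(spans$doc_id, documents$doc_id)
  note(is.na(idx), "unknown doc_id")
  len <- nchar(documents$text)[idx]
  known <- !is.na(idx)
  note(known & spans$start < 0L, "negative start")
  note(known & spans$start >= spans$end, "empty span (start >= end)")
  note(known & spans$start < spans$end & spans$end > len, "end beyond text length")
  inb <- known & spans$start >= 0L & spans$start < spans$end & spans$end <= len
  got <- rep(NA_character_, nrow(spans))
  got[inb] <- slice_text(documents$text[idx[inb]], spans$start[inb], spans$end[inb])
  note(inb & !is.na(spans$surface) & spans$surface != got,
       "surface does not match text slice")
  note(!is.na(spans$confidence) & (spans$confidence < 0 | spans$confidence > 1),
       "confidence outside [0, 1]")
  key <- paste(spans$doc_id, spans$annotator, spans$start, spans$end, spans$label)
  note(duplicated(key) | duplicated(key, fromLast = TRUE), "duplicate span")
  if (length(out)) bind_rows(out) else {
    tibble(doc_id = character(), start = integer(), end = integer(),
           label = character(), problem = character())
  }
}

#' Lint annotations against the harmonized annotation guidelines
#'
#' Two closed rules derived from the harmonization of annotator
#' disagreements in German clinical text:
#'
#' * `COMPOUND_SPLIT` — a compound word (anatomy fused with a symptom in a
#'   single token, e.g. "Rückenschmerzen") must be annotated as one span.
#'   The finding fires when an ANATOMY span is immediately adjacent to a
#'   SYMPTOM span (no intervening character) and the concatenation forms a
#'   single whitespace-free token of the text.
#' * `SLASH_LIST_MERGED` — slash-separated anatomy lists ("Rücken/Hüft")
#'   must be annotated as separate spans; a single ANATOMY span whose
#'   surface contains "/" violates this.
#'
#' @param documents Corpus tibble.
#' @param spans Span table (assumed valid, see [validate_spans()]).
#' @return A tibble of findings: `doc_id`, `rule_id`, `start`, `end`,
#'   `message`.
#' @export
lint_guidelines <- function(documents, spans) {
  spans <- materialize_surface(as_span_tbl(spans), documents)
  findings <- list()
  add <- function(doc_id, rule_id, start, end, message) {
    findings[[length(findings) + 1L]] <<- tibble(
      doc_id = doc_id, rule_id = rule_id, start = start, end = end,
      message = message
    )
  }

  slash <- spans$label == "ANATOMY" & grepl("/", spans$surface, fixed = TRUE)
  for (k in which(slash)) {
    add(spans$doc_id[k], "SLASH_LIST_MERGED", spans$start[k], spans$end[k],
        sprintf("ANATOMY span \"%s\" holds a slash-separated list; annotate each anatomy separately",
                spans$surface[k]))
  }

  for (d in unique(spans$doc_id)) {
    text <- documents$text[match(d, documents$doc_id)]
    ss <- spans[spans$doc_id == d, , drop = FALSE]
    ana <- ss[ss$label == "ANATOMY", , drop = FALSE]
    sym <- ss[ss$label == "SYMPTOM", , drop = FALSE]
    if (!nrow(ana) || !nrow(sym)) next
    for (i in seq_len(nrow(ana))) {
      ## adjacency in either order: anatomy|symptom or symptom|anatomy
      j <- which(sym$start == ana$end[i] | sym$end == ana$start[i])
      for (k in j) {
        lo <- min(ana$start[i], sym$start[k]); hi <- max(ana$end[i], sym$end[k])
        piece <- slice_text(text, lo, hi)
        before <- if (lo > 0L) slice_text(text, lo - 1L, lo) else ""
        after <- if (hi < nchar(text)) slice_text(text, hi, hi + 1L) else ""
        one_token <- !grepl("\\s", piece) &&
          !grepl("^\\p{L}", after, perl = TRUE) && !grepl("\\p{L}$", before, perl = TRUE)
        if (one_token) {
          add(d, "COMPOUND_SPLIT", lo, hi,
              sprintf("compound token \"%s\" split into ANATOMY + SYMPTOM; annotate compounds in a single span",
                      piece))
        }
      }
    }
  }
  if (length(findings)) bind_rows(findings) else {
    tibble(doc_id = character(), rule_id = character(), start = integer(),
           end = integer(), message = character())
  }
}
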