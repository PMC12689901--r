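#' Tokenize a narrative
#'
#' Deterministic, dependency-free tokenizer: maximal runs of characters that
#' are neither whitespace nor splitting punctuation, plus each punctuation
#' mark (`. , ; : ! ? / ( ) "`) as its own single-character token. The slash
#' is a separator so that slash-separated anatomy lists ("Rücken/Hüft")
#' tokenize into their parts; German compounds ("Kopfschmerzen") remain
#' single tokens. Concatenating token surfaces with the skipped whitespace
#' reconstructs the text.
#'
#' @param text A single narrative string.
#' @return A tibble with columns `token`, `start`, `end` (0-based,
#'   half-open character offsets), ordered by `start`.
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[^\\s.,;:!?/()\"]+|[.,;:!?/()\"]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  tibble(token = slice_text(text, start, end), start = start, end = end)
}

#' Encode spans as a token-level IOB tag sequence
#'
#' A token receives the `B-`/`I-` tags of a span's label iff it overlaps
#' that span by at least one character: the first overlapping token is
#' tagged `B-<label>`, subsequent ones `I-<label>`, and all other tokens
#' `O`. A span that cuts through a token therefore widens to the whole
#' token. Two same-label spans overlapping the same token cannot be encoded
#' and raise an error; overlapping spans of different labels are resolved by
#' precedence (earlier span start wins for the shared token).
#'
#' @param tokens Token tibble from [tokenize()].
#' @param spans Span table for the same document.
#' @return A tibble of class `iob_sequence`: `token`, `start`, `end`, `tag`,
#'   with the document id in attribute `doc_id`.
#' @export
spans_to_iob <- function(tokens, spans) {
  spans <- as_span_tbl(spans)
  if (length(unique(spans$doc_id)) > 1L) {
    stop_validation("spans_to_iob() encodes one document at a time")
  }
  tags <- rep("O", nrow(tokens))
  owner <- rep(NA_integer_, nrow(tokens))
  ord <- order(spans$start, spans$end)
  for (k in ord) {
    hit <- which(tokens$start < spans$end[k] & tokens$end > spans$start[k])
    if (!length(hit)) next
    clash <- hit[!is.na(owner[hit])]
    if (length(clash)) {
      same <- spans$label[owner[clash]] == spans$label[k]
      if (any(same)) {
        stop_validation(sprintf(
          "ambiguous encoding: two %s spans overlap token \"%s\" [%d, %d)",
          spans$label[k], tokens$token[clash[same][1]],
          tokens$start[clash[same][1]], tokens$end[clash[same][1]]))
      }
      hit <- hit[is.na(owner[hit])]  # different label: earlier span keeps the token
      if (!length(hit)) next
    }
    owner[hit] <- k
    tags[hit] <- paste0(c("B-", rep("I-", length(hit) - 1L)), spans$label[k])
  }
  out <- tokens
  out$tag <- tags
  structure(out, class = c("iob_sequence", class(tokens)),
            doc_id = spans$doc_id[1] %||% NA_character_)
}

#' Decode an IOB tag sequence into spans
#'
#' Each maximal `B-`/`I-` run of one label becomes a span from the first
#' token's start to the last token's end. Ill-formed sequences are repaired
#' first: an orphan `I-` (following `O`, the sequence start, or a tag of a
#' different label) is treated as `B-` and counted in the `repairs`
#' attribute of the result (with a warning).
#'
#' @param tokens Token tibble (or an `iob_sequence`, in which case `tags`
#'   may be omitted).
#' @param tags Character vector of IOB tags, one per token.
#' @param doc_id Document id stamped on the decoded spans.
#' @param text Optional document text used to materialize surfaces
#'   (including inter-token whitespace); token surfaces are pasted otherwise.
#' @return A span table; attribute `repairs` counts repaired orphan tags.
#' @export
iob_to_spans <- function(tokens, tags = NULL, doc_id = NULL, text = NULL) {
  if (is.null(tags)) {
    if (!inherits(tokens, "iob_sequence")) {
      stop_validation("`tags` is required unless `tokens` is an iob_sequence")
    }
    tags <- tokens$tag
    doc_id <- doc_id %||% attr(tokens, "doc_id")
  }
  doc_id <- doc_id %||% NA_character_
  if (length(tags) != nrow(tokens)) {
    stop_validation("length(tags) must equal the number of tokens")
  }

  prefix <- sub("-.*$", "", tags)
  lab <- ifelse(prefix == "O", NA_character_, sub("^[BI]-", "", tags))
  bad <- !(tags == "O" | grepl("^[BI]-", tags) & lab %in% ENTITY_LABELS)
  if (any(bad)) {
    stop_validation(sprintf("malformed IOB tag(s): %s",
                            paste(unique(tags[bad]), collapse = ", ")))
  }

  repairs <- 0L
  for (i in seq_along(tags)) {
    if (prefix[i] == "I") {
      prev_ok <- i > 1L && prefix[i - 1L] != "O" && identical(lab[i - 1L], lab[i])
      if (!prev_ok) {
        prefix[i] <- "B"
        repairs <- repairs + 1L
      }
    }
  }
  if (repairs > 0L) {
    warn(sprintf("repaired %d orphan I- tag(s) to B-", repairs))
  }

  rows <- list()
  i <- 1L
  n <- length(tags)
  while (i <= n) {
    if (prefix[i] == "B") {
      j <- i
      while (j < n && prefix[j + 1L] == "I" && identical(lab[j + 1L], lab[i])) j <- j + 1L
      rows[[length(rows) + 1L]] <- tibble(
        doc_id = doc_id, start = tokens$start[i], end = tokens$end[j], label = lab[i]
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  spans <- if (length(rows)) as_span_tbl(bind_rows(rows)) else clin_spans()
  spans$surface <- if (!is.null(text)) {
    slice_text(text, spans$start, spans$end)
  } else if (nrow(spans)) {
    vapply(seq_len(nrow(spans)), function(k) {
      hit <- tokens$start >= spans$start[k] & tokens$end <= spans$end[k]
      paste(tokens$token[hit], collapse = " ")
    }, character(1))
  } else {
    character()
  }
  attr(spans, "repairs") <- repairs
  spans
}

#' Export a corpus as CoNLL-style token/tag text
#'
#' One token per line as `surface<TAB>tag`, with a blank line between
#' documents, in corpus order.
#'
#' @param documents Corpus tibble.
#' @param spans Span table covering the corpus.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return The CoNLL lines (invisibly when written to `path`).
#' @export
write_conll <- function(documents, spans, path = NULL) {
  spans <- as_span_tbl(spans)
  blocks <- lapply(seq_len(nrow(documents)), function(i) {
    toks <- tokenize(documents$text[i])
    iob <- spans_to_iob(toks, spans[spans$doc_id == documents$doc_id[i], , drop = FALSE])
    paste0(iob$token, "\t", iob$tag)
  })
  lines <- unlist(lapply(blocks, c, ""), use.names = FALSE)
  lines <- head(lines, -1L)  # no trailing blank line
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}
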