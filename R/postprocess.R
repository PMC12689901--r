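#' Postprocessing configuration
#'
#' Tunable parameters for turning raw predicted spans into affirmed-symptom
#' records.
#'
#' @param confidence_threshold Minimum span confidence retained, in
#'   `[0, 1]`. Default 0.5; spans without a confidence are retained and
#'   flagged rather than dropped.
#' @param negation_window Maximum number of tokens allowed between a
#'   negation cue and the symptom it negates (cue before symptom). Default
#'   3, wide enough for a determiner/adjective between cue and noun while
#'   staying inside a short clause.
#' @param clause_bounded Whether a sentence/clause boundary (`. ; :`)
#'   between cue and symptom blocks negation. Default `TRUE`.
#' @param fusion_window How many extracted entities before/after a bare pain
#'   mention are searched for an anatomical reference. Default 1 (the
#'   adjacent entity on either side, same clause).
#' @param pain_lexemes Lowercase lexemes identifying pain mentions; a
#'   surface equal to a lexeme is a bare pain term, a longer surface ending
#'   in one is already a compound and is left untouched.
#' @return A list of class `postprocess_config`.
#' @export
postprocess_config <- function(confidence_threshold = 0.5,
                               negation_window = 3L,
                               clause_bounded = TRUE,
                               fusion_window = 1L,
                               pain_lexemes = c("schmerz", "schmerzen")) {
  confidence_threshold <- check_fraction(confidence_threshold, "confidence_threshold")
  if (negation_window < 0L || fusion_window < 0L) {
    stop_validation("windows must be >= 0")
  }
  structure(
    list(confidence_threshold = confidence_threshold,
         negation_window = as.integer(negation_window),
         clause_bounded = isTRUE(clause_bounded),
         fusion_window = as.integer(fusion_window),
         pain_lexemes = tolower(pain_lexemes)),
    class = "postprocess_config"
  )
}

#' Filter spans by confidence
#'
#' Retains exactly the spans whose confidence is at least `tau`. Spans
#' lacking a confidence score are retained and flagged in the `unscored`
#' column (a backend that emits no scores should not lose all its output to
#' the filter).
#'
#' @param spans Span table.
#' @param tau Threshold in `[0, 1]`.
#' @return The retained spans with an added logical `unscored` column.
#' @export
filter_confidence <- function(spans, tau = 0.5) {
  tau <- check_fraction(tau, "tau")
  spans <- as_span_tbl(spans)
  spans$unscored <- is.na(spans$confidence)
  spans[spans$unscored | spans$confidence >= tau, , drop = FALSE]
}

## clause boundary characters that block negation scope and fusion
CLAUSE_BOUNDARY <- c(".", ";", ":")

has_clause_boundary <- function(text, from, to) {
  if (to <= from) return(FALSE)
  grepl("[.;:]", slice_text(text, from, to))
}

#' Flag negated symptom spans
#'
#' A SYMPTOM span is negated iff a NEGATION cue precedes it within
#' `negation_window` tokens and (when `clause_bounded`) no sentence or
#' clause boundary (`. ; :`) intervenes. One cue may negate several
#' coordinated symptoms inside its clause ("no swelling, redness" style
#' coordination stays within the token window).
#'
#' @param text The document narrative.
#' @param spans Span table for that document including NEGATION and SYMPTOM
#'   spans.
#' @param config A [postprocess_config()].
#' @return `spans` with logical column `negated` (`FALSE` for non-symptom
#'   rows) and `cue_start` giving the negating cue's offset (NA if none).
#' @export
detect_negated <- function(text, spans, config = postprocess_config()) {
  spans <- as_span_tbl(spans)
  toks <- tokenize(text)
  spans$negated <- FALSE
  spans$cue_start <- NA_integer_
  sym <- which(spans$label == "SYMPTOM")
  cues <- which(spans$label == "NEGATION")
  for (i in sym) {
    for (k in cues) {
      if (spans$end[k] > spans$start[i]) next  # cue must precede the symptom
      between <- sum(toks$start >= spans$end[k] & toks$end <= spans$start[i])
      if (between > config$negation_window) next
      if (config$clause_bounded &&
          has_clause_boundary(text, spans$end[k], spans$start[i])) next
      spans$negated[i] <- TRUE
      spans$cue_start[i] <- spans$start[k]
      break
    }
  }
  spans
}

is_bare_pain <- function(surface, lexemes) {
  tolower(trimws(surface)) %in% lexemes
}

is_pain_compound <- function(surface, lexemes) {
  s <- tolower(trimws(surface))
  out <- rep(FALSE, length(s))
  for (lex in lexemes) {
    out <- out | (endsWith(s, lex) & nchar(s) > nchar(lex))
  }
  out
}

#' Fuse bare pain mentions with a neighboring anatomical reference
#'
#' A SYMPTOM span whose surface is a bare pain lexeme ("Schmerzen") is
#' uninformative on its own. For each such span, the nearest ANATOMY span
#' among the adjacent extracted entities (up to `fusion_window` entities
#' before or after, preceding preferred, same clause) is fused into a
#' compound surface: anatomy + lowercased pain term, so "Kopf" + "Schmerzen"
#' becomes "Kopfschmerzen". Surfaces that are already compounds (ending in a
#' pain lexeme with at least one preceding character) are left untouched;
#' bare pain mentions with no anatomy in reach are flagged `generic_pain`.
#' Each anatomy fuses at most one symptom; consumed anatomies are marked.
#'
#' @param text The document narrative.
#' @param spans Span table for that document.
#' @param config A [postprocess_config()].
#' @return `spans` with columns `surface_out` (the fused or original
#'   surface), `fused`, `generic_pain`, and `consumed` (anatomy used up by a
#'   fusion).
#' @export
fuse_pain_anatomy <- function(text, spans, config = postprocess_config()) {
  spans <- as_span_tbl(spans)
  miss <- is.na(spans$surface)
  spans$surface[miss] <- slice_text(text, spans$start[miss], spans$end[miss])
  spans$surface_out <- spans$surface
  spans$fused <- FALSE
  spans$generic_pain <- FALSE
  spans$consumed <- FALSE

  ents <- which(spans$label %in% c("SYMPTOM", "ANATOMY"))
  ents <- ents[order(spans$start[ents])]
  pos <- match(seq_len(nrow(spans)), ents)  # row -> position in entity order

  for (i in ents[spans$label[ents] == "SYMPTOM"]) {
    if (!is_bare_pain(spans$surface[i], config$pain_lexemes)) next
    p <- pos[i]
    offsets <- seq_len(config$fusion_window)
    candidates <- as.vector(rbind(-offsets, offsets))  # prefer preceding at each distance
    anat <- NA_integer_
    for (off in candidates) {
      q <- p + off
      if (q < 1L || q > length(ents)) next
      j <- ents[q]
      if (spans$label[j] != "ANATOMY" || spans$consumed[j]) next
      lo <- min(spans$end[i], spans$end[j]); hi <- max(spans$start[i], spans$start[j])
      if (has_clause_boundary(text, lo, hi)) next
      anat <- j
      break
    }
    if (is.na(anat)) {
      spans$generic_pain[i] <- TRUE
    } else {
      spans$surface_out[i] <- paste0(spans$surface[anat], tolower(spans$surface[i]))
      spans$fused[i] <- TRUE
      spans$consumed[anat] <- TRUE
    }
  }
  spans
}

#' Standardize a symptom surface form
#'
#' Strips punctuation (`. : , ; ! ?`), collapses internal whitespace,
#' lowercases, then capitalizes the first letter ("HUSTEN:" becomes
#' "Husten"). Idempotent.
#'
#' @param term Character vector of raw surfaces.
#' @return Cleaned terms; an error if any term is empty after cleaning.
#' @export
standardize_surface <- function(term) {
  if (any(is.na(term) | !nzchar(term))) {
    stop_validation("cannot standardize an empty term")
  }
  out <- gsub("[.:,;!?]", "", term)
  out <- trimws(gsub("\\s+", " ", out))
  if (any(!nzchar(out))) {
    stop_validation(sprintf("term empty after cleaning: %s",
                            paste(shQuote(term[!nzchar(out)]), collapse = ", ")))
  }
  upfirst(tolower(out))
}

#' Load a symptom normalization dictionary
#'
#' A dictionary maps canonical symptom terms to enumerated variants
#' (synonyms and inflected forms, e.g. "Verstopfung" to the canonical
#' "Obstipation", "gehustet" to "Husten"); matching is case-insensitive.
#' Inflections are enumerated, not stemmed, to keep the mapping auditable.
#' Invariants enforced at load time: no variant may map to two canonicals,
#' and every canonical is a variant of its own entry.
#'
#' @param x Path to a two-column TSV (`canonical<TAB>variant`, one variant
#'   per line, `#` comments allowed), a path to a JSON object
#'   (canonical -> array of variants), a named list, or a data frame with
#'   columns `canonical` and `variant`.
#' @return A tibble of class `symptom_dictionary` with columns `canonical`
#'   and `variant`.
#' @export
read_symptom_dictionary <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_io(sprintf("no such dictionary file: %s", x))
    if (grepl("\\.json$", x, ignore.case = TRUE)) {
      x <- jsonlite::fromJSON(x, simplifyVector = TRUE)
    } else {
      df <- read.delim(x, header = FALSE, comment.char = "#",
                       col.names = c("canonical", "variant"),
                       fileEncoding = "UTF-8", stringsAsFactors = FALSE)
      x <- df
    }
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- tibble(
      canonical = rep(names(x), lengths(x)),
      variant = unlist(x, use.names = FALSE)
    )
  }
  dict <- as_tibble(x)[, c("canonical", "variant")]
  ## every canonical is a valid variant of itself (self entries first so a
  ## lowercase duplicate never shadows the canonical spelling)
  self <- tibble(canonical = unique(dict$canonical), variant = unique(dict$canonical))
  dict <- unique(bind_rows(self, dict))
  key <- tolower(dict$variant)
  clash <- tapply(dict$canonical, key, function(v) length(unique(v)) > 1L)
  if (any(clash)) {
    stop_validation(sprintf("variant(s) mapped to multiple canonicals: %s",
                            paste(names(clash)[clash], collapse = ", ")))
  }
  dict <- dict[!duplicated(key), , drop = FALSE]
  structure(dict, class = c("symptom_dictionary", class(dict)))
}

#' The shipped default German symptom dictionary
#'
#' A small dictionary of common emergency-department symptoms with attested
#' synonym and inflection pairs (e.g. Verstopfung/Obstipation,
#' husten/gehustet). Editable: see
#' `system.file("extdata", "symptom_dictionary.tsv", package = "clinspan")`.
#'
#' @return A `symptom_dictionary` tibble.
#' @export
default_symptom_dictionary <- function() {
  read_symptom_dictionary(
    system.file("extdata", "symptom_dictionary.tsv", package = "clinspan")
  )
}

#' Map a standardized term to its canonical symptom
#'
#' Case-insensitive lookup of the term among the dictionary variants;
#' unmatched terms are returned unchanged (symptoms outside the dictionary
#' retain their original name). Idempotent given a dictionary whose
#' canonicals are their own variants (enforced at load).
#'
#' @param term Character vector of surface-standardized terms.
#' @param dictionary A `symptom_dictionary`.
#' @return Character vector of canonical (or unchanged) terms.
#' @export
normalize_symptom <- function(term, dictionary = default_symptom_dictionary()) {
  hit <- match(tolower(term), tolower(dictionary$variant))
  out <- term
  out[!is.na(hit)] <- dictionary$canonical[hit[!is.na(hit)]]
  out
}

#' Extract affirmed symptom records from predicted spans
#'
#' The full postprocessing pipeline, applied in order: confidence filtering,
#' negation detection, anatomy-pain fusion, surface standardization, and
#' dictionary normalization. Fusion changes surfaces, never the number of
#' symptom records, so `affirmed + negated` equals the number of symptom
#' spans surviving the confidence filter. The confidence filter is applied
#' to SYMPTOM spans only: NEGATION and ANATOMY spans are context, and
#' discarding a low-confidence cue would silently turn an excluded symptom
#' into an affirmed one (it also makes the affirmed set shrink monotonically
#' as the threshold rises).
#'
#' @param documents Corpus tibble (or a single-row corpus).
#' @param spans Predicted (or gold) span table covering the corpus.
#' @param config A [postprocess_config()].
#' @param dictionary A `symptom_dictionary`.
#' @param include_negated Return negated records too (flagged in the
#'   `negated` column) instead of affirmed records only.
#' @return A tibble of symptom records: `doc_id`, `standardized_term`,
#'   `raw_surface`, `negated`, `start`, `end`, `confidence`, plus the
#'   pipeline flags `fused`, `generic_pain`, `unscored`.
#' @export
extract_affirmed <- function(documents, spans, config = postprocess_config(),
                             dictionary = default_symptom_dictionary(),
                             include_negated = FALSE) {
  spans <- as_span_tbl(get_spans(spans))
  miss <- is.na(spans$surface)
  if (any(miss)) {
    spans[miss, "surface"] <- materialize_surface(spans[miss, , drop = FALSE],
                                                  documents)$surface
  }
  ## the confidence filter applies to symptom spans only: negation cues and
  ## anatomies are context, and dropping a low-confidence cue would flip its
  ## symptom to affirmed (breaking monotonicity in the threshold, and unsafe)
  sym <- spans$label == "SYMPTOM"
  kept_sym <- filter_confidence(spans[sym, , drop = FALSE],
                                config$confidence_threshold)
  ctx <- spans[!sym, , drop = FALSE]
  ctx$unscored <- is.na(ctx$confidence)
  kept <- bind_rows(kept_sym, ctx)
  kept <- kept[order(match(kept$doc_id, documents$doc_id), kept$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(documents))) {
    d <- documents$doc_id[i]
    text <- documents$text[i]
    ss <- kept[kept$doc_id == d, , drop = FALSE]
    if (!nrow(ss)) next
    ss <- detect_negated(text, ss, config)
    ss <- fuse_pain_anatomy(text, ss, config)
    sym <- ss[ss$label == "SYMPTOM", , drop = FALSE]
    if (!nrow(sym)) next
    out[[length(out) + 1L]] <- tibble(
      doc_id = d,
      standardized_term = normalize_symptom(standardize_surface(sym$surface_out),
                                            dictionary),
      raw_surface = sym$surface,
      negated = sym$negated,
      start = sym$start, end = sym$end,
      confidence = sym$confidence,
      fused = sym$fused, generic_pain = sym$generic_pain,
      unscored = sym$unscored
    )
  }
  records <- if (length(out)) bind_rows(out) else tibble(
    doc_id = character(), standardized_term = character(),
    raw_surface = character(), negated = logical(), start = integer(),
    end = integer(), confidence = numeric(), fused = logical(),
    generic_pain = logical(), unscored = logical()
  )
  if (include_negated) records else records[!records$negated, , drop = FALSE]
}
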