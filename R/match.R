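## ---- assignment core -------------------------------------------------------
##
## One-to-one gold/prediction assignment per document. Eligible pairs and
## their credit depend on the granularity:
##   STRICT  : exact boundaries; correct label => COR (credit 1),
##             wrong label => INC (credit 0, still a matched pair)
##   EXACT   : exact boundaries, label ignored => COR
##   PARTIAL : any character overlap; exact boundaries => COR (credit 1),
##             otherwise => PAR (partial credit, default 0.5); label ignored
##   TYPE    : same label and overlap >= type_overlap_min characters => COR
## Unassigned gold spans are MIS, unassigned predictions SPU. The assignment
## maximizes total credit exactly (maximum-weight bipartite matching); INC
## pairs carry an epsilon weight so they are matched when doing so costs no
## credit. Candidate edges are ordered by (exactness, overlap length,
## leftmost gold start, shortest gold span) for deterministic tie-breaking.

match_counts <- function(gs, ge, gl, ps, pe, pl, granularity,
                         type_overlap_min = 1L) {
  ng <- length(gs); np <- length(ps)
  counts <- c(COR = 0L, INC = 0L, PAR = 0L, MIS = ng, SPU = np)
  if (ng == 0L || np == 0L) return(counts)

  ov <- pmax(outer(ge, pe, pmin) - outer(gs, ps, pmax), 0L)
  exact <- outer(gs, ps, "==") & outer(ge, pe, "==")
  labm <- outer(gl, pl, "==")

  eps <- 1e-6
  if (granularity == "STRICT") {
    elig <- exact
    w <- ifelse(labm, 1, eps)
    cat_cor <- labm
  } else if (granularity == "EXACT") {
    elig <- exact
    w <- matrix(1, ng, np)
    cat_cor <- elig
  } else if (granularity == "PARTIAL") {
    elig <- ov > 0L
    w <- ifelse(exact, 1, 0.5)
    cat_cor <- exact
  } else if (granularity == "TYPE") {
    elig <- labm & ov >= type_overlap_min
    w <- matrix(1, ng, np)
    cat_cor <- elig
  } else {
    stop_validation(sprintf("unknown granularity: %s", granularity))
  }

  idx <- which(elig)
  if (!length(idx)) return(counts)
  gi <- ((idx - 1L) %% ng) + 1L
  pj <- ((idx - 1L) %/% ng) + 1L
  ord <- order(-exact[idx], -ov[idx], gs[gi], ge[gi] - gs[gi], ps[pj])
  gi <- gi[ord]; pj <- pj[ord]; wt <- w[idx][ord]

  ## fast path: the candidate edges already form a matching
  if (!anyDuplicated(gi) && !anyDuplicated(pj)) {
    mg <- gi; mp <- pj
  } else {
    g <- igraph::make_bipartite_graph(
      c(rep(FALSE, ng), rep(TRUE, np)),
      edges = as.vector(rbind(gi, ng + pj))
    )
    m <- igraph::max_bipartite_match(g, weights = wt, eps = 1e-9)$matching
    mg <- which(!is.na(m[seq_len(ng)]))
    mp <- m[mg] - ng
  }

  if (length(mg)) {
    cor <- cat_cor[cbind(mg, mp)]
    counts["COR"] <- sum(cor)
    if (granularity == "STRICT") counts["INC"] <- sum(!cor)
    if (granularity == "PARTIAL") counts["PAR"] <- sum(!cor)
    counts["MIS"] <- ng - length(mg)
    counts["SPU"] <- np - length(mg)
  }
  counts
}

#' Match predicted spans against gold spans at one granularity
#'
#' Builds a one-to-one assignment between gold and predicted spans of a
#' single document and tallies the five MUC/SemEval-style categories:
#' correct (COR), boundary-matched with wrong type (INC, strict regime
#' only), partial boundary overlap (PAR), missing gold (MIS), and spurious
#' prediction (SPU). The assignment maximizes matching credit (COR plus
#' partial credit for PAR) exactly, with deterministic tie-breaking by
#' exactness, overlap length, leftmost gold start, and shortest span.
#'
#' @param gold,pred Span tables for the same single document.
#' @param granularity One of [granularities()].
#' @param type_overlap_min Minimum character overlap required by the TYPE
#'   regime ("some overlap" is not quantified in the evaluation standard;
#'   default 1 character).
#' @return An object of class `match_result`: the five counts plus
#'   `granularity`, `label_scope`, `n_gold`, `n_pred`.
#' @export
match_spans <- function(gold, pred, granularity = GRANULARITIES,
                        type_overlap_min = 1L) {
  granularity <- match.arg(granularity)
  gold <- as_span_tbl(gold); pred <- as_span_tbl(pred)
  docs <- unique(c(gold$doc_id, pred$doc_id))
  if (length(docs) > 1L) {
    stop_validation(sprintf("match_spans() scores one document at a time; got: %s",
                            paste(docs, collapse = ", ")))
  }
  for (side in list(gold = gold, pred = pred)) {
    if (anyDuplicated(side[c("start", "end", "label")])) {
      stop_validation("duplicate (start, end, label) triples are not allowed")
    }
  }
  counts <- match_counts(gold$start, gold$end, gold$label,
                         pred$start, pred$end, pred$label,
                         granularity, type_overlap_min)
  structure(
    list(counts = counts, granularity = granularity, label_scope = "ALL",
         n_gold = nrow(gold), n_pred = nrow(pred)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s (%s): ", x$granularity, x$label_scope))
  cat(paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "), "\n")
  invisible(x)
}

#' Precision, recall, and F1 from matching counts
#'
#' With partial credit `w` for PAR pairs:
#' `precision = (COR + w*PAR) / (COR + INC + PAR + SPU)` and
#' `recall    = (COR + w*PAR) / (COR + INC + PAR + MIS)`;
#' F1 is the harmonic mean of the two. A zero denominator yields 0 with
#' `flagged = TRUE` (empty scope).
#'
#' @param match_result A `match_result`, or a named vector/list with
#'   entries COR, INC, PAR, MIS, SPU.
#' @param partial_credit Credit for PAR pairs, in `[0, 1]`; default 0.5
#'   (set to 1 for full credit).
#' @return A list with `precision`, `recall`, `f1`, `flagged`.
#' @export
compute_metrics <- function(match_result, partial_credit = 0.5) {
  partial_credit <- check_fraction(partial_credit, "partial_credit")
  counts <- if (inherits(match_result, "match_result")) match_result$counts else match_result
  counts <- unlist(counts)[c("COR", "INC", "PAR", "MIS", "SPU")]
  credit <- counts[["COR"]] + partial_credit * counts[["PAR"]]
  pden <- counts[["COR"]] + counts[["INC"]] + counts[["PAR"]] + counts[["SPU"]]
  rden <- counts[["COR"]] + counts[["INC"]] + counts[["PAR"]] + counts[["MIS"]]
  flagged <- pden == 0 || rden == 0
  p <- if (pden > 0) credit / pden else 0
  r <- if (rden > 0) credit / rden else 0
  list(precision = p, recall = r, f1 = f1_score(p, r), flagged = flagged)
}

#' Harmonic mean of precision and recall
#'
#' `F1 = 2PR / (P + R)`, balancing how many extracted entities were correct
#' (precision) against how many relevant entities were captured (recall);
#' 0 when both are 0.
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return Numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  s <- precision + recall
  ifelse(s > 0, 2 * precision * recall / s, 0)
}

## pull a span table out of whatever annotation container the user passed
get_spans <- function(x) {
  if (inherits(x, "doccano_corpus")) return(x$spans)
  if (is.list(x) && !is.data.frame(x) && !is.null(x$spans)) return(as_span_tbl(x$spans))
  as_span_tbl(x)
}

#' Score a predicted annotation set against gold across a corpus
#'
#' Micro-aggregates matching counts over all documents, per entity label and
#' pooled over all labels (`ALL`), at all four granularities — the same
#' entity-by-granularity layout as a model-validation table. Per-label rows
#' restrict both gold and predictions to that label before matching.
#'
#' @param gold,pred Span tables (or `doccano_corpus` objects). Every
#'   prediction's `doc_id` must be covered by the gold side; gold documents
#'   with no predictions count as missed.
#' @param granularity Subset of [granularities()] to report.
#' @param labels Entity labels to report individually (besides `ALL`).
#' @param partial_credit Credit for PAR pairs, see [compute_metrics()].
#' @param type_overlap_min See [match_spans()].
#' @return A tibble of class `metric_report`: one row per (label,
#'   granularity) with precision, recall, f1 (full precision), `support`
#'   (gold span count), the five counts, and the empty-scope flag.
#' @export
evaluate_corpus <- function(gold, pred, granularity = GRANULARITIES,
                            labels = ENTITY_LABELS, partial_credit = 0.5,
                            type_overlap_min = 1L) {
  gold <- get_spans(gold); pred <- get_spans(pred)
  granularity <- match.arg(granularity, several.ok = TRUE)
  missing_docs <- setdiff(pred$doc_id, gold$doc_id)
  if (length(missing_docs)) {
    stop_validation(sprintf(
      "predictions reference documents absent from the gold set: %s",
      paste(missing_docs, collapse = ", ")))
  }

  doc_ids <- unique(gold$doc_id)
  g_by <- split(seq_len(nrow(gold)), factor(gold$doc_id, levels = doc_ids))
  p_by <- split(seq_len(nrow(pred)), factor(pred$doc_id, levels = doc_ids))
  scopes <- c("ALL", labels)
  acc <- array(0L, dim = c(length(scopes), length(granularity), 5L),
               dimnames = list(scopes, granularity, c("COR", "INC", "PAR", "MIS", "SPU")))

  for (d in doc_ids) {
    gi <- g_by[[d]]; pi <- p_by[[d]]
    for (sc in scopes) {
      gsel <- if (sc == "ALL") gi else gi[gold$label[gi] == sc]
      psel <- if (sc == "ALL") pi else pi[pred$label[pi] == sc]
      for (gr in granularity) {
        acc[sc, gr, ] <- acc[sc, gr, ] + match_counts(
          gold$start[gsel], gold$end[gsel], gold$label[gsel],
          pred$start[psel], pred$end[psel], pred$label[psel],
          gr, type_overlap_min
        )
      }
    }
  }

  rows <- list()
  for (sc in scopes) {
    for (gr in granularity) {
      counts <- acc[sc, gr, ]
      m <- compute_metrics(counts, partial_credit)
      rows[[length(rows) + 1L]] <- tibble(
        label = sc, granularity = gr,
        precision = m$precision, recall = m$recall, f1 = m$f1,
        support = unname(counts["COR"] + counts["INC"] + counts["PAR"] + counts["MIS"]),
        cor = unname(counts["COR"]), inc = unname(counts["INC"]),
        par = unname(counts["PAR"]), mis = unname(counts["MIS"]),
        spu = unname(counts["SPU"]), flagged = m$flagged
      )
    }
  }
  out <- bind_rows(rows)
  structure(out, class = c("metric_report", class(out)),
            partial_credit = partial_credit, type_overlap_min = type_overlap_min)
}

#' Inter-annotator agreement as entity-level F1
#'
#' Treats annotator A as the reference and annotator B as the prediction and
#' scores all four granularities. Entity-level F1 suits span annotation
#' tasks better than document-level chance-corrected statistics; swapping
#' the annotators leaves F1 unchanged and exchanges precision with recall.
#'
#' @param annotations_a,annotations_b Span tables (or `doccano_corpus`
#'   objects) from the two annotators, covering the same documents.
#' @param ... Passed on to [evaluate_corpus()].
#' @return A `metric_report` tibble.
#' @export
interannotator_agreement <- function(annotations_a, annotations_b, ...) {
  evaluate_corpus(annotations_a, annotations_b, ...)
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  cat("<metric_report> micro-averaged, partial credit =",
      attr(x, "partial_credit") %||% 0.5, "\n")
  wide <- report_f1_summary(x)
  print.data.frame(as.data.frame(wide), digits = digits + 1, row.names = FALSE)
  invisible(x)
}

#' F1 summary by label and granularity
#'
#' Pivots a metric report into one row per label with one F1 column per
#' granularity — the grouped-bar layout used to compare backends.
#'
#' @param report A `metric_report`.
#' @param metric Which metric to pivot (`"f1"`, `"precision"`, `"recall"`).
#' @return A wide tibble, labels in rows, granularities in columns.
#' @export
report_f1_summary <- function(report, metric = "f1") {
  df <- as_tibble(report)[, c("label", "granularity", metric)]
  tidyr::pivot_wider(df, names_from = "granularity",
                     values_from = tidyr::all_of(metric))
}

#' Write a metric report as TSV and JSON twins
#'
#' The TSV holds one row per (label, granularity, metric) with values at
#' full precision (render with 2 decimals for display); leading `#` comment
#' lines carry provenance (seed and configuration hash). The JSON twin
#' carries the same rows plus the provenance as a `meta` object.
#'
#' @param report A `metric_report`.
#' @param path Output path without extension; `.tsv` and `.json` are added.
#' @param meta Named list of provenance fields to embed (e.g. seed,
#'   config_hash).
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_metric_report <- function(report, path, meta = list()) {
  long <- tidyr::pivot_longer(
    as_tibble(report)[, c("label", "granularity", "precision", "recall", "f1", "support")],
    cols = c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value"
  )
  tsv <- paste0(path, ".tsv")
  header <- sprintf("# %s: %s", names(meta), vapply(meta, format, character(1)))
  con <- file(tsv, open = "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  if (length(header)) writeLines(header, con)
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  json <- paste0(path, ".json")
  jsonlite::write_json(
    list(meta = meta, rows = long),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(tsv = tsv, json = json))
}
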