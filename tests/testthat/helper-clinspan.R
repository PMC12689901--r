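# shared fixtures and independent oracles, all built in code

# the published worked-example narrative (English translation) with its gold
# entity set: five symptom mentions, two of them negated
table2_fixture <- function() {
  narrative <- paste(
    "4 weeks ago surgery for colon Ca with artificial exit on the right.",
    "In case of closure, resurgery with inpatient stay up to 2 weeks ago.",
    "For days significant Swelling of the right lower leg with redness and overheating.",
    "No dyspnea, no thoracic pain."
  )
  loc <- function(x) as.integer(gregexpr(x, narrative, fixed = TRUE)[[1]][1]) - 1L
  surfaces <- c("Swelling", "redness", "overheating", "dyspnea", "thoracic pain")
  starts <- vapply(surfaces, loc, integer(1))
  cue_no1 <- loc("No ")
  cue_no2 <- loc(" no ") + 1L
  spans <- clin_spans(
    doc_id = "t2",
    start = c(starts, cue_no1, cue_no2),
    end = c(starts + nchar(surfaces), cue_no1 + 2L, cue_no2 + 2L),
    label = c(rep("SYMPTOM", 5), "NEGATION", "NEGATION"),
    surface = c(surfaces, "No", "no")
  )
  list(documents = clin_corpus("t2", narrative), spans = spans)
}

# random span set on one document; caller controls the RNG state
random_spans <- function(doc_id = "d", n_max = 8L, text_len = 30L) {
  n <- sample.int(n_max + 1L, 1L) - 1L
  if (n == 0L) return(clin_spans())
  start <- sample.int(text_len - 1L, n, replace = TRUE) - 1L
  len <- sample.int(8L, n, replace = TRUE)
  end <- pmin(start + len, text_len)
  label <- sample(entity_labels(), n, replace = TRUE)
  sp <- clin_spans(doc_id, start, end, label)
  sp[!duplicated(sp[c("start", "end", "label")]), , drop = FALSE]
}

# independent oracle: maximum assignment credit by exhaustive subset DP over
# the prediction side, with pair credits taken straight from the granularity
# definitions (exact boundaries / boundary overlap / entity type)
oracle_best_credit <- function(gold, pred, granularity, partial_credit = 0.5,
                               type_overlap_min = 1L) {
  ng <- nrow(gold); np <- nrow(pred)
  if (ng == 0L || np == 0L) return(0)
  stopifnot(np <= 16L)
  w <- matrix(0, ng, np)
  for (i in seq_len(ng)) {
    for (j in seq_len(np)) {
      ov <- min(gold$end[i], pred$end[j]) - max(gold$start[i], pred$start[j])
      ex <- gold$start[i] == pred$start[j] && gold$end[i] == pred$end[j]
      lm <- gold$label[i] == pred$label[j]
      w[i, j] <- switch(granularity,
        STRICT = if (ex && lm) 1 else 0,
        EXACT = if (ex) 1 else 0,
        PARTIAL = if (ex) 1 else if (ov > 0) partial_credit else 0,
        TYPE = if (lm && ov >= type_overlap_min) 1 else 0
      )
    }
  }
  n_mask <- bitwShiftL(1L, np)
  dp <- rep(0, n_mask)  # dp[mask+1]: best credit using pred subset `mask`
  for (i in seq_len(ng)) {
    if (all(w[i, ] == 0)) next
    nxt <- dp
    for (j in seq_len(np)) {
      if (w[i, j] == 0) next
      bit <- bitwShiftL(1L, j - 1L)
      free <- which(bitwAnd(seq_len(n_mask) - 1L, bit) == 0L)
      nxt[free + bit] <- pmax(nxt[free + bit], dp[free] + w[i, j])
    }
    dp <- nxt
  }
  max(dp)
}

# matching credit achieved by the package's assignment
match_credit <- function(mr, partial_credit = 0.5) {
  unname(mr$counts["COR"] + partial_credit * mr$counts["PAR"])
}

local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  set.seed(seed)
}
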