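---
title: "Span matching, negation scoping, and the synthetic evaluation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Span matching, negation scoping, and the synthetic evaluation harness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinspan)
```

`clinspan` turns span-annotated clinical free text into structured records of
affirmed symptoms and evaluates arbitrary named-entity recognition (NER)
backends against gold annotations. This vignette documents the methods: the
matching model behind the four evaluation granularities, the negation and
fusion rules, the synthetic corpus and its corruption model with closed-form
expected metrics, and the design decisions taken where the underlying
methodology left the choice open.

## Annotation model

A corpus is a set of documents (id, UTF-8 narrative, free-form metadata). An
annotation is a **span**: a 0-based, half-open character interval
`[start, end)` with one of three labels — `SYMPTOM`, `ANATOMY`, `NEGATION` —
an optional confidence in [0, 1], and the materialized surface
`text[start:end]`. Spans are contiguous; discontinuous entities are not
modeled. Overlapping spans of different labels are allowed (a cue may abut a
symptom); exact duplicate `(start, end, label)` triples are rejected.

Two harmonized annotation guidelines for German are enforced by a linter
rather than by construction, because they are exactly the cases where human
annotators diverge:

* `COMPOUND_SPLIT`: a compound token fusing anatomy and symptom
  ("Rückenschmerzen") must be one span, not `ANATOMY("Rücken")` +
  `SYMPTOM("schmerzen")`.
* `SLASH_LIST_MERGED`: slash-separated anatomy lists ("Rücken/Hüft") must be
  separate `ANATOMY` spans, not one.

The IOB codec tokenizes by whitespace plus split-off punctuation
(`. , ; : ! ? / ( ) "`); the slash is a separator so slash lists tokenize
into their parts, while compounds stay single tokens. A span that cuts
through a token widens to the whole token when encoded (the decoded span is
the minimal token-aligned superset, never narrower). Decoding repairs orphan
`I-` tags to `B-` and counts the repairs — tolerant decoding suits imperfect
model output better than rejection.

## The four matching granularities

Predictions are compared to gold with the five-category counting scheme used
in classic NER evaluations (correct, wrong-type, partial, missing, spurious),
with 0.5 partial credit by default:

$$P = \frac{COR + w\,PAR}{COR + INC + PAR + SPU},\qquad
  R = \frac{COR + w\,PAR}{COR + INC + PAR + MIS},\qquad
  F_1 = \frac{2PR}{P+R}.$$

Eligible gold–prediction pairs per granularity: STRICT and EXACT pair only
spans with identical boundaries (STRICT additionally requires the label for
`COR`; a boundary match with the wrong label is `INC`); PARTIAL pairs any
overlapping spans (exact boundaries give `COR`, other overlaps `PAR`), labels
ignored; TYPE pairs same-label spans overlapping by at least
`type_overlap_min` characters (default 1 — "some overlap" is not quantified
in the evaluation standard, so the threshold is exposed as configuration).
Counts are micro-aggregated (pooled) across documents, per label and overall;
micro-averaging is the NER standard and is stable for rare labels. Whether
partial overlaps earn 0.5 or full credit is configurable (`partial_credit`),
0.5 being the default.

**Assignment.** The pairing is a one-to-one assignment solved exactly as a
maximum-weight bipartite matching (weights 1 for `COR`, `w` for `PAR`, and an
infinitesimal weight for `INC` pairs so they are matched when doing so costs
no credit), with candidate edges ordered by exactness, overlap length,
leftmost gold start, and shortest span for deterministic tie-breaking. A
purely greedy pass over that same ordering was considered and rejected: on
feasible inputs it is suboptimal — e.g. gold $g_1=[0,10)$, $g_2=[11,20)$ and
predictions $p_1=[5,15)$, $p_2=[0,3)$, where greedy pairs $(g_1,p_1)$ for
credit 0.5 while the optimum $(g_1,p_2),(g_2,p_1)$ scores 1.0 — and a
suboptimal matcher can even violate the granularity ordering
$F_1(\text{STRICT}) \le F_1(\text{EXACT}) \le F_1(\text{PARTIAL})$. With the
exact optimum both properties hold by construction (the eligible-pair sets
are nested and partial credit only adds weight), and the test suite verifies
optimality against an exhaustive subset-DP oracle on a thousand random
documents. Ties between equally optimal assignments can split counts
differently (one `COR` + `MIS` + `SPU` versus two `PAR`) but never change
precision, recall, or F1.

Inter-annotator agreement is the same computation with annotator A as
reference; which annotator serves as reference is arbitrary, and F1 is
invariant under the swap (precision and recall exchange). Entity-level F1 is
used instead of document-level chance-corrected agreement because the unit of
interest is the span, not the document.

## Postprocessing to affirmed symptoms

`extract_affirmed()` applies, in order:

1. **Confidence filter** (`confidence_threshold`, default τ = 0.5; no
   threshold is canonical, 0.5 is the natural midpoint and fully
   configurable). Spans without scores are kept and flagged, so unscored
   backends lose nothing. The filter applies to SYMPTOM spans only:
   negation cues and anatomies are *context*, and dropping a low-confidence
   cue would silently flip its symptom from excluded to affirmed — both
   clinically unsafe and a violation of the natural monotonicity requirement
   that the affirmed set can only shrink as τ rises.
2. **Negation scoping**. A symptom is negated iff a `NEGATION` cue precedes
   it within `negation_window` tokens (default 3: determiner/adjective
   distance inside a short clause) with no clause boundary (`. ; :`) between
   cue and symptom. Commas do not block, so one cue distributes over
   coordination ("keine Übelkeit, Schwindel"). The methodology source never
   specifies how a cue binds to its symptom (adjacency? parse?); this
   pre-posed, clause-bounded window is the simplest rule that reproduces the
   published worked example and is fully configurable.
3. **Anatomy–pain fusion**. A symptom whose surface is a bare pain lexeme
   ("Schmerzen" and inflections; the lexeme list ships and is editable) is
   fused with the nearest `ANATOMY` among the adjacent extracted entities
   (up to `fusion_window` = 1 entity before or after, preceding preferred,
   same clause): "Kopf" + "Schmerzen" → "Kopfschmerzen". A surface already
   ending in a pain lexeme with at least one preceding character is a
   compound and stays untouched; bare pain with no anatomy in reach is kept
   and flagged generic. Fusion rewrites surfaces, never record counts, so
   `affirmed + negated` always equals the number of filtered symptom spans.
4. **Surface standardization**: strip `. : , ; ! ?`, collapse whitespace,
   lowercase, capitalize the first letter. Idempotent.
5. **Dictionary normalization**: case-insensitive lookup among enumerated
   variants (synonyms and inflections; no stemmer, so the mapping stays
   auditable); unmatched terms keep their original name. The shipped default
   dictionary covers common ED symptoms with attested pairs such as
   Verstopfung→Obstipation and gehustet→Husten.

## Backends

Everything that can map a document to spans is a backend:
`ner_backend(name, predict)`. The shipped **lexicon backend** is a
longest-match, case-insensitive, word-bounded scanner (confidence 1.0 for an
exact case match, 0.8 otherwise) — deterministic, dependency-free, and
perfect by construction on corpora generated from its own lexicon, which
makes it the end-to-end smoke test. The **generative adapter**
(`llm_backend`) owns the three-part zero-shot prompt (entity definitions,
worked examples, fixed closing instruction requesting reasoning plus a
Python-style list), robust parsing of the *last* list literal in the response
(failures are flagged data, not errors), and grounding of entity strings to
character offsets by case-insensitive search (every non-overlapping
occurrence becomes a span). Strings that cannot be located are excluded and
reported rather than scored as spurious, because an unlocatable string has no
defensible boundary. The completion function is supplied by the caller
(e.g. a wrapper around a local HTTP endpoint), keeping all text on premises;
no model weights or network clients ship with the package. A fine-tuned
token classifier plugs in the same way: wrap its inference function.

## The synthetic corpus and its corruption model

The generator emulates the *structural* phenomena of short German ED
anamnesis texts — 1–5 clauses per narrative drawn from templates for affirmed
symptoms, negated symptoms ("Keine Übelkeit."), compound pain
("Kopfschmerzen seit gestern."), separate anatomy+pain ("Schmerzen im
Rücken."), and slash anatomy lists ("Rücken/Hüft und Kopfschmerzen seit
heute.") — with gold spans exact by construction and guideline-conformant by
default (a non-conformant mode produces the linter's target violations).
Defaults: 150 documents, `p_negation = 0.3`, `p_compound = 0.5`,
`p_slash_list = 0.1`, a small embedded lexicon of common ED symptoms and
anatomies. It does **not** emulate clinical realism: no typos, no free word
order, no discontinuous or ambiguous mentions, no annotator noise, uniform
metadata. Passing tests therefore demonstrate the *machinery* (offset
arithmetic, matching optimality, scope rules, closed-form calibration), not
performance on real clinical language.

The corruption model degrades gold into synthetic predictions with mutually
exclusive per-span branches: dropped with probability $m$, else
boundary-shifted with probability $s$ (one token edge by default, so shifted
spans stay token-aligned, remain non-empty, and always still overlap their
source), else label-flipped with probability $t$ (boundaries kept), else
copied exactly. Spurious token-aligned spans are added per document at
Poisson rate $\lambda$ and never overlap gold. Because gold spans are
disjoint, a shifted span can never coincide with a *different* gold span's
boundaries, which keeps the expectations exact:

$$R_{\text{STRICT}} = (1-m)(1-s)(1-t), \quad
  R_{\text{EXACT}} = (1-m)(1-s),$$
$$R_{\text{PARTIAL}} = (1-m)\big((1-s) + w\,s\big), \quad
  R_{\text{TYPE}} = (1-m)\big(s + (1-s)(1-t)\big),$$

at the pooled all-labels scope (label flips keep exact boundaries, so PARTIAL
and EXACT — which ignore the label — still count them; per-label scoping
would multiply in $(1-t)$ instead). Expected precision divides the same
credit by the expected prediction count $N(1-m) + D\lambda$ for $N$ gold
spans over $D$ documents. Standard errors: recall credit per gold span is an
i.i.d. variable on $\{0, w, 1\}$, giving $\mathrm{se}(R) = \sigma/\sqrt{N}$;
precision is a ratio with a random denominator, handled by the delta method
with $\mathrm{Cov}(S, M) = N\mu m$ (credit implies survival); F1 by
first-order propagation through the harmonic mean including the positive
P–R covariance. The calibration test requires agreement within three
standard errors on a ≥1,000-span corpus for each rate in isolation.

## Numerical choices and degenerate inputs

* Zero denominators in precision/recall yield 0 with an explicit
  `flagged = TRUE` (empty scope), never `NaN`.
* Metric values are kept at full precision; report writers and print methods
  round to two decimals for display only.
* The `INC` epsilon weight ($10^{-6}$) is far below the smallest credit
  difference (0.5) at any feasible document size, so it can never trade
  against credit.
* The matcher takes a fast path when candidate pairs are conflict-free (the
  overwhelmingly common case) and calls the exact matching solver otherwise.
* Unknown entity labels in input files are collected and reported, not
  silently dropped and not fatal; malformed JSON lines and out-of-bounds
  offsets are fatal with line/document context.
* The validation split holds out `floor(fraction * n)` seeded-sampled
  documents (15 % of 150 → 22); the rounding rule is a documented choice.
* Seeded code paths save and restore the caller's RNG state.

## Problem sizes in the test suite

The suite exercises: optimality against the exhaustive oracle on 1,000
random documents of up to 8×8 spans; granularity monotonicity on 10,000
random cases; calibration on a ~1,400-span corpus per corruption rate; and
full-corpus round trips on a 150-document fixture. These sizes give
comfortable statistical resolution (3-SE bands of roughly ±0.03 on recall)
while keeping the default test run fast.

## Known limitations

* Negation handling is a window rule, not scope parsing: post-posed negation
  ("Schmerzen werden verneint") and double negation are out of reach.
* The normalization dictionary is enumerative; unseen inflections pass
  through unchanged (by design, but it bounds recall of normalization).
* Confidence semantics are backend-defined; the filter assumes comparability
  across spans of one backend, nothing more.
* The synthetic corpus cannot certify performance on real clinical German;
  it certifies the evaluation and postprocessing machinery around any real
  backend.
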