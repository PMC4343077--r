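---
title: "Phenotype concept recognition: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype concept recognition: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorec)
library(dplyr)
```

## The problem

Phenotype concept recognition (CR) locates mentions of human phenotypic
abnormalities in free text *and* resolves each mention to a concept in the
Human Phenotype Ontology (HPO) — as opposed to plain named-entity
recognition, which only locates. Phenotype mentions are hard targets:
their lexical structure is complex (quality–entity noun phrases such as
"bell-shaped thorax"), their token order varies ("Hypoplasia of the optic
nerve" vs. "Optic nerve hypoplasia"), and coordination compresses several
concepts into one phrase ("short and broad fingers"). `phenorec`
implements a full toolchain around this task: an ontology-derived lexicon
and recognizer, an exact-boundary span evaluator, and a generator of
stratified lexical test suites for standardized error analysis.

## The recognition model

The recognizer is dictionary-based. Every non-obsolete concept
contributes its preferred label, plus synonyms in the admitted scopes, as
lexicon entries. Each entry carries two keys:

* its **normalized token sequence** — tokens lower-cased, singularized
  and mapped through a derivational table, order preserved — used for
  exact-surface matching, and
* its **token signature** — the multiset of normalized content tokens
  with stop tokens removed, serialized as the sorted sequence — used for
  order-invariant matching.

Scanning is greedy, left to right, longest window first, with windows of
up to `max_window_tokens = 14` tokens (HPO label lengths range from 1 to
14 tokens). Windows never cross punctuation and must start and end on a
content token. For each window the exact map is consulted first, then
(when `order_invariant` is on) the signature map; concepts found only via
the signature are tagged `ORDER_INVARIANT`. After a match the scan
resumes at the next token. When one signature maps to several concepts
the default emits all candidates and lets overlap resolution tie-break;
`ambiguous = "none"` is a strict mode that emits nothing for such
windows.

Two further passes run per sentence (sentences are split at `.?!`
followed by an upper-case word):

**Coordination decomposition.** Conjunct lists joined by commas, "and" or
"or" are segmented into an optional qualifier prefix, the conjuncts, and
an optional shared tail; the segmentation maximizing the number of
conjuncts whose (qualifier + conjunct + tail) combination resolves in the
index is chosen (ties prefer the smallest shared parts). Two output
shapes mirror the gold-standard annotation guidelines:

* *qualifier preceding* the conjunction — "synostosis of some carpal and
  tarsal bones" — or a shared plain entity head following it — "short and
  broad fingers" — yields **one full span** carrying the concept of each
  resolving conjunct;
* *qualifier succeeding* the conjunction, where the shared tail's head
  noun is a quality noun ("malformations", "hypoplasia", ...), yields
  **nested suffix spans**: "branchial arch, otic and renal malformations"
  produces three annotations with a shared right boundary.

The quality-noun list is a plain-text resource; the decision between the
two shapes is exactly "is the shared tail a quality noun". A
decomposition is emitted only when at least two conjuncts resolve — a
phrase like "meningioma and short stature" is two independent mentions,
not a coordination. Mixed patterns with resolvable material on both sides
are treated as qualifier-preceding; the gold guidelines do not cover
them, so this is flagged here rather than silently guessed.

**Non-canonical phenotypes** (off by default, as in the systems this
models): a small registry of shallow clause patterns — `ENTITY copula
QUALIFIER(-list)` and `ENTITY verb QUALIFIER` — rewrites "fingers are
short and broad" to "short fingers" / "broad fingers", resolves each
rewrite, and emits the clause span. Gold corpora built under
canonical-form guidelines exclude such spans, hence the default.

**Overlap resolution.** Where overlapping candidates map to
hierarchically related concepts the longer span wins; on identical spans
the deeper (more specific) concept wins, with the lexicographic CURIE as
the final deterministic tie-break. Unrelated concepts on one span are all
kept — multi-annotation is intentional (a span can legitimately denote
two concepts). Nested suffix spans from coordination are exempt from
suppression, since the guidelines require them.

Negated mentions ("no kidney anomalies were found") are annotated like
any other: negation is a downstream concern, and suppression here would
make gold alignment impossible.

## Normalization choices

* **Offsets** are 0-based, half-open, character-based everywhere;
  `substr(text, start + 1, end)` reconstructs every span.
* **Stop tokens** default to the six prepositions the criterion families
  test (in, of, to, by, from, with), the articles (the, a, an), and a
  small quantifier set (some, several, many, few, multiple, most, any,
  both). The quantifiers are included because gold spans such as
  "synostosis of *some* carpal and tarsal bones" must resolve to concepts
  whose labels carry no quantifier; they are harmless elsewhere because
  signatures only ever drop them. "and"/"or" are deliberately *not* stop
  tokens — they carry coordination structure.
* **Plural stripping** is rule-based (`-ies`, `-es` after sibilants,
  bare `-s`) with an irregular table (vertebrae, teeth, ...); tokens
  ending in `-ss`, `-us`, `-is` are protected so "synostosis" and
  "pectus" survive. A full lemmatizer is unnecessary at the lexicon's
  morphological range and would add a heavy dependency.
* **Derivational variants** (hypoplastic→hypoplasia, otic→ear,
  malformation/anomaly→abnormality, ...) live in a versioned TSV resource
  that users can extend; the pipeline is idempotent by construction and
  the tests enforce that every table target is a fixed point.
  A `renal→kidney` mapping is deliberately absent by default: it would
  make "renal malformations" and "kidney anomalies" collide on concepts
  that HPO distinguishes.
* Matching is case-insensitive; numerals are matched verbatim; Roman
  numeral detection covers I–XX.

## Evaluation model

Alignment is instance-level and exact: a predicted instance is correct
iff start, end and concept id all equal a gold instance, each instance
matched at most once. There is no overlap or partial credit —
decomposition guidelines make fine-grained spans part of the task, and
exact boundaries deliberately penalize systems that emit concepts nested
inside a provided label. A gold span carrying two concepts counts as two
instances. Duplicate identical predictions are deduplicated before
alignment. `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`, with 0/0
defined as 0; rounding (half-up, two decimals) happens only at the
presentation layer.

Stratification maps every instance to the top-level categories (direct
children of HP:0000118 by default) on any ancestry path of its concept; a
multi-parent concept such as Dense calvaria (skeletal *and* head-and-neck)
counts once per stratum, so per-stratum counts need not sum to the
overall counts. Out-of-subtree concepts land in an `uncategorized`
stratum.

## The test-suite generator

Each criterion isolates one lexical property: fourteen length bins,
punctuation, isolated Arabic/Roman numerals, stop words, singular/plural
inflection, adjective↔noun lexical variation, the canonical-order mirror
pair, synonym substitution, and synthesized coordinations. Each entry is
one whole-document phrase with its expected annotations; suites are run
one entry per document and scored with the same exact-boundary
alignment.

Generation is seeded and deterministic. Mirror pairs
({singular, plural}, {canonical, transformed}) are sampled once per pair
from a shared group seed, so the two suites are in bijection over the
same concepts — a system that truly handles order-free matching should
score identically on both. The generator never emits an unsolvable
entry: a transformed phrase is kept only if its signature resolves to
exactly the expected concept, and synthesized coordinations only if
every (shared part + conjunct) combination resolves uniquely and the two
concepts are hierarchically unrelated. Non-English and metaphoric
constructs ("bone-in-bone appearance") cannot be synthesized faithfully
from an ontology, so those families accept curated input lists only and
are skipped (with a warning) otherwise.

## The bundled fixtures

The package bundles a synthetic mini-ontology (36 stanzas) in the HPO id
space: a category skeleton under HP:0000118, the multi-parent Dense
calvaria example, synonyms and derivational pairs sufficient for every
worked example above, and one obsolete term. Concepts that the
literature discusses without printing an id use a reserved `HP:02000xx`
range; hierarchy placements are simplified. The six-document fixture
gold corpus exercises each annotation guideline (canonical form, both
coordination shapes, retained negation, transformed order). Offsets in
the fixture corpus are computed at build time, never hand-typed.

What passing against these fixtures shows — and what it does not: the
fixtures verify the *mechanics* (boundary arithmetic, decomposition
shapes, order-invariance, scoring) at small scale. They do not emulate
the ambiguity load, synonym sparsity, acronyms, hedging or
annotation-inconsistency of a real 200-abstract corpus, where
dictionary recognizers of this family score in the 0.45–0.56 F range
rather than near 1.0. Problem sizes throughout (a ~35-concept ontology,
6 documents, a few hundred suite entries) were chosen as the smallest
that exercise every code path.

## Known limitations

* No acronym expansion ("BDA1") — out of scope for dictionary matching
  without a synonym listing the acronym.
* Complex concept conjunctions that need human interpretation
  ("stereotyped jerky movements" ≈ two concepts with interleaved tokens)
  are not attempted.
* Coordination segmentation is shallow; qualifier material on *both*
  sides of a conjunct list is resolved as qualifier-preceding rather
  than split.
* Sentence segmentation is heuristic (`.?!` + capital); abbreviations
  ending a token ("e.g.") can split early, which only shortens the
  window a coordination pass may consider.
* The tokenizer is whitespace-plus-punctuation; corpora tokenized under
  different conventions may disagree on token counts for length-binned
  criteria.

## A worked example

```{r example}
store <- fixture_concept_store()
index <- build_index(build_lexicon(store), store)
annotate_text("branchial arch, otic and renal malformations", index)

gold <- fixture_gold_corpus()
pred <- annotate_corpus(gold$documents, index)
report <- evaluate_corpus(gold, pred, assign_categories(store))
glance(report)
```
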