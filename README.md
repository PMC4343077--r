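# phenorec

Phenotype concept recognition (CR) for Human Phenotype Ontology (HPO)
style ontologies, with exact-boundary evaluation and stratified lexical
test suites for standardized error analysis.

Phenotype CR means locating mentions of phenotypic abnormalities in free
text **and** resolving each mention to an ontology concept — not just
tagging entity spans. The mentions are lexically awkward: token order
varies ("Hypoplasia of the optic nerve" ↔ "Optic nerve hypoplasia"),
adjective and noun forms alternate ("hypoplastic nails" ↔ "nail
hypoplasia"), and coordination compresses several concepts into one
phrase. `phenorec` is aimed at biomedical text-mining practitioners who
need (i) a transparent dictionary recognizer with those behaviours,
(ii) a strict evaluator against standoff gold corpora, and (iii) a
generator of criterion-stratified test suites that turns error analysis
into something reproducible.

## What it implements

**Recognition.** A lexicon is built from an OBO ontology (labels +
synonyms by scope). Each surface form is indexed twice: by its
normalized token sequence and by its order-free *token signature* — the
multiset of normalized content tokens. A greedy longest-match scan (up
to 14-token windows) emits `EXACT_SURFACE` and `ORDER_INVARIANT`
matches; a coordination pass decomposes conjunct lists following the
standard gold annotation guidelines (qualifier-preceding → one full span
with all concepts; qualifier-succeeding → nested suffix spans); an
optional pass rewrites non-canonical clauses ("fingers are short and
broad"). Overlaps among hierarchically related concepts resolve to the
longer span, then the more specific concept. Negated mentions are kept.

**Evaluation.** Exact-boundary, instance-level alignment:

    P = TP/(TP+FP)    R = TP/(TP+FN)    F = 2PR/(P+R)

with 0/0 → 0, no overlap or partial credit, and stratification by
top-level category (direct children of `HP:0000118`), counting
multi-parent concepts once per category.

**Test suites.** Criterion families after the software-testing approach
to CR error analysis: label-length bins (1–14 tokens), punctuation,
Arabic/Roman numerals, stop words, singular/plural, lexical variation,
canonical vs. transformed token order (a mirror pair), synonyms, and
synthesized coordinations. Generation is seeded; every emitted entry is
guaranteed solvable against the lexicon.

Everything ships with a self-contained synthetic fixture ontology and a
six-document fixture gold corpus, so nothing needs to be downloaded.

## Worked example

```r
library(phenorec)

store <- fixture_concept_store()
index <- build_index(build_lexicon(store), store)

annotate_text("branchial arch, otic and renal malformations", index)
#> # A tibble: 3 × 6
#>   doc_id start   end matched_text                                 concept_id match_type
#>   <chr>  <int> <int> <chr>                                        <chr>      <chr>
#> 1 doc        0    44 branchial arch, otic and renal malformations HP:0009794 COORDINATION
#> 2 doc       16    44 otic and renal malformations                 HP:0000598 COORDINATION
#> 3 doc       25    44 renal malformations                          HP:0000792 COORDINATION
```

One coordinated phrase, three annotation instances: the whole span is a
branchial-arch anomaly, the suffix starting at "otic" is an ear
abnormality, and the innermost suffix is a renal malformation — the
nested-span shape the gold guidelines prescribe. Evaluating the
recognizer against the bundled gold corpus:

```r
gold <- fixture_gold_corpus()
pred <- annotate_corpus(gold$documents, index)
report <- evaluate_corpus(gold, pred, assign_categories(store))
glance(report)
#> # A tibble: 1 × 6
#>      TP    FP    FN precision recall f_score
#>   <int> <int> <int>     <dbl>  <dbl>   <dbl>
#> 1    10     0     0         1      1       1
```

All 10 gold instances are recovered with exact boundaries (the fixture
corpus is deliberately small and unambiguous; real-corpus scores for
dictionary recognizers of this family are far lower). `tidy(report)`
gives per-category rows and `autoplot(report)` plots them; test suites
work the same way via `generate_testsuite()` → `run_testsuite()` →
`tidy()` / `glance()` / `autoplot()`.

A thin command-line wrapper is available at `exec/phenorec`
(subcommands `fixture`, `lexicon`, `annotate`, `evaluate`, `testsuite`,
`pipeline`), writing standoff TSV annotations and JSON/TSV reports with
full provenance (version, config hash, seed).

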