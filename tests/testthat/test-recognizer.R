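test_that("every lexicon entry is findable by its own surface", {
  for (i in seq_len(nrow(fx$lexicon))) {
    ids <- phenorec:::index_exact_ids(fx$index, fx$lexicon$norm_seq[i])
    expect_true(fx$lexicon$concept_id[i] %in% ids)
  }
  sig_ids <- phenorec:::index_sig_ids(fx$index,
                                      signature_key("type a1 brachydactyly"))
  expect_equal(sig_ids, "HP:0009371")
})

test_that("the index is a multimap: shared signatures preserve ambiguity", {
  amb <- read_obo(lines = c(
    "[Term]", "id: HP:0000001", "name: Short finger", "",
    "[Term]", "id: HP:0000002", "name: Finger short"))
  lx <- build_lexicon(amb, fx$config)
  ix <- build_index(lx, amb, fx$config)
  hits <- phenorec:::index_sig_ids(ix, signature_key("short finger"))
  expect_setequal(hits, c("HP:0000001", "HP:0000002"))
  # default mode emits all candidates; strict mode emits none
  ann_all <- annotate_text("short finger", ix)
  expect_setequal(ann_all$concept_id, c("HP:0000001", "HP:0000002"))
  ann_none <- annotate_text("short finger", ix,
                            options = recognizer_options(ambiguous = "none"))
  expect_equal(nrow(ann_none), 0L)
})

test_that("negation does not suppress annotation (guideline: annotate anyway)", {
  ann <- annotate_text("no kidney anomalies were found", fx$index)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$matched_text, "kidney anomalies")
  expect_equal(ann$concept_id, "HP:0000077")
})

test_that("order-invariant matching recovers transformed canonical order", {
  on <- annotate_text("Brachydactyly type A1", fx$index)
  expect_true("HP:0009371" %in% on$concept_id)
  expect_equal(on$match_type[on$concept_id == "HP:0009371"], "ORDER_INVARIANT")
  off <- annotate_text("Brachydactyly type A1", fx$index,
                       options = recognizer_options(order_invariant = FALSE))
  expect_false("HP:0009371" %in% off$concept_id)
  # only the verbatim sub-surface "Brachydactyly" can still match exactly
  expect_true(all(off$match_type == "EXACT_SURFACE"))
  expect_equal(off$matched_text, "Brachydactyly")
})

test_that("injection-recovery: every unambiguous surface is recovered exactly", {
  sig_counts <- table(unique(fx$lexicon[c("signature", "concept_id")])$signature)
  for (i in seq_len(nrow(fx$lexicon))) {
    s <- fx$lexicon$surface[i]
    if (sig_counts[[fx$lexicon$signature[i]]] != 1) next
    text <- paste0("Patient shows ", s, " .")
    ann <- annotate_text(text, fx$index)
    expect_equal(nrow(ann), 1L, info = s)
    expect_equal(ann$start, 14L, info = s)
    expect_equal(ann$end, 14L + nchar(s), info = s)
    expect_equal(ann$concept_id, fx$lexicon$concept_id[i], info = s)
  }
})

test_that("order-invariance property: content permutations round-trip", {
  multi <- dplyr::filter(fx$lexicon, provenance == "LABEL", token_count >= 2)
  sig_counts <- table(unique(fx$lexicon[c("signature", "concept_id")])$signature)
  withr::with_seed(3, {
    for (i in seq_len(nrow(multi))) {
      if (sig_counts[[multi$signature[i]]] != 1) next
      content <- token_signature(multi$surface[i])
      if (any(content %in% c("and", "or"))) next  # permutation may break syntax
      perm <- paste(sample(content), collapse = " ")
      on <- annotate_text(perm, fx$index)
      expect_true(multi$concept_id[i] %in% on$concept_id, info = perm)
      # exact matching is normalization-equivalent, so only permutations
      # matching no entry's normalized order need order-invariant mode
      concept_seqs <- fx$lexicon$norm_seq[fx$lexicon$concept_id ==
                                            multi$concept_id[i]]
      if (!perm %in% concept_seqs) {
        off <- annotate_text(perm, fx$index,
                             options = recognizer_options(order_invariant = FALSE,
                                                          coordination = FALSE))
        expect_false(multi$concept_id[i] %in%
                       off$concept_id[off$start == 0 & off$end == nchar(perm)],
                     info = perm)
      }
    }
  })
})

test_that("longest match wins and scanning resumes after a match", {
  ann <- annotate_text("Brachydactyly type 3 was present", fx$index)
  expect_equal(ann$matched_text, "Brachydactyly type 3")
  expect_equal(ann$concept_id, "HP:0200006")  # not the nested Brachydactyly
})

test_that("non-canonical clauses are matched only when enabled", {
  on <- recognizer_options(non_canonical = TRUE)
  ann <- annotate_text("fingers are short and broad", fx$index, options = on)
  expect_setequal(ann$concept_id, c("HP:0009381", "HP:0001500"))
  expect_equal(unique(ann$matched_text), "fingers are short and broad")
  expect_true(all(ann$match_type == "NON_CANONICAL"))

  ann2 <- annotate_text("nails were hypoplastic", fx$index, options = on)
  expect_equal(ann2$concept_id, "HP:0200002")
  off <- annotate_text("nails were hypoplastic", fx$index)
  expect_equal(nrow(off), 0L)
  # unresolvable rewrite: unknown entity yields nothing
  none <- annotate_text("gizzards are short and broad", fx$index, options = on)
  expect_equal(nrow(none), 0L)
})

test_that("overlap resolution keeps the more specific concept on equal spans", {
  # BROAD synonym gives the child the same signature as its parent's label
  ann <- annotate_text("kidney anomalies", fx$index_broad)
  expect_equal(ann$concept_id, "HP:0000792")
  # hierarchically unrelated concepts on one span are all kept
  amb <- read_obo(lines = c(
    "[Term]", "id: HP:0000001", "name: Short finger", "",
    "[Term]", "id: HP:0000002", "name: Finger short"))
  ix <- build_index(build_lexicon(amb, fx$config), amb, fx$config)
  both <- annotate_text("short finger", ix)
  expect_equal(nrow(both), 2L)
  # disjoint spans are untouched
  two <- annotate_text("Meningioma was found. Short stature was noted.",
                       fx$index)
  expect_setequal(two$concept_id, c("HP:0002858", "HP:0004322"))
})

test_that("coordination full spans suppress their nested plain matches", {
  ann <- annotate_text("She had short and broad fingers.", fx$index)
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$concept_id, c("HP:0009381", "HP:0001500"))
  expect_equal(unique(ann$matched_text), "short and broad fingers")
})

test_that("annotation output is deterministic and offset-faithful", {
  docs <- fixture_gold_corpus()$documents
  a1 <- annotate_corpus(docs, fx$index)
  a2 <- annotate_corpus(docs, fx$index)
  expect_identical(a1, a2)
  txt <- setNames(docs$text, docs$doc_id)
  expect_equal(substr(txt[a1$doc_id], a1$start + 1, a1$end), unname(a1$matched_text),
               ignore_attr = TRUE)
  expect_true(all(a1$start < a1$end))
})

test_that("empty and whitespace documents produce no annotations", {
  expect_equal(nrow(annotate_text("", fx$index)), 0L)
  expect_equal(nrow(annotate_text("   ", fx$index)), 0L)
})
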