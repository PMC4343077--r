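test_that("label classification is deterministic per family definitions", {
  expect_true("length_01" %in% classify_label("Meningioma"))
  expect_true("stopword" %in% classify_label("Abnormality of the kidney"))
  expect_true("stopword" %in% classify_label("Thumb with broad tip"))
  expect_true("roman_numeral" %in% classify_label("Short metacarpal IV"))
  expect_true("arabic_numeral" %in% classify_label("Brachydactyly type 3"))
  expect_true("punctuation" %in% classify_label("Aplasia/Hypoplasia of the nails"))
  # hyphen alone is not punctuation for this criterion
  expect_false("punctuation" %in% classify_label("Bell-shaped thorax"))
})

test_that("canonical-order transformation reorders with identical signature", {
  expect_equal(transform_canonical_order("Hypoplasia of the optic nerve"),
               "Optic nerve hypoplasia")
  expect_equal(transform_canonical_order("Type A1 brachydactyly"),
               "Brachydactyly type A1")
  expect_equal(transform_canonical_order("Brachydactyly type 3"),
               "Type 3 brachydactyly")
  expect_true(is.na(transform_canonical_order("Meningioma")))
  lbls <- c("Hypoplasia of the optic nerve", "Abnormality of the kidney",
            "Type A1 brachydactyly")
  for (l in lbls) {
    expect_equal(signature_key(transform_canonical_order(l)), signature_key(l))
  }
})

test_that("head-noun inflection touches only the head and skips no-ops", {
  expect_equal(inflect_label("Hypoplastic nail", "PLURAL"), "Hypoplastic nails")
  expect_equal(inflect_label("Short fingers", "SINGULAR"), "Short finger")
  expect_equal(inflect_label("Hypoplasia of the optic nerve", "PLURAL"),
               "Hypoplasia of the optic nerves")
  expect_true(is.na(inflect_label("Short fingers", "PLURAL")))    # already plural
  expect_true(is.na(inflect_label("Short metacarpal IV", "PLURAL")))  # numeral head
})

test_that("coordination synthesis follows the guideline semantics", {
  e <- synthesize_coordination("HP:0009381", "HP:0001500", "QUAL_FIRST", "and",
                               lexicon = fx$lexicon)
  expect_equal(e$input_text, "Short and broad fingers")
  exp <- e$expected[[1]]
  expect_equal(nrow(exp), 2L)
  expect_equal(unique(exp$start), 0L)
  expect_equal(unique(exp$end), nchar(e$input_text))
  expect_setequal(exp$concept_id, c("HP:0009381", "HP:0001500"))

  b <- synthesize_coordination("HP:0009794", "HP:0000792", "QUAL_LAST", "and",
                               lexicon = fx$lexicon)
  expect_true(grepl(" and ", b$input_text))
  expect_true(oracle_entry_solvable(b$input_text, b$expected[[1]]))
  bexp <- dplyr::arrange(b$expected[[1]], start)
  expect_equal(bexp$concept_id, c("HP:0009794", "HP:0000792"))
  expect_equal(bexp$start[1], 0L)
  expect_gt(bexp$start[2], 0L)
  expect_equal(unique(bexp$end), nchar(b$input_text))

  # concepts sharing no component: precondition violation, skip
  expect_null(synthesize_coordination("HP:0002858", "HP:0009381",
                                      "QUAL_FIRST", "and",
                                      lexicon = fx$lexicon))
})

test_that("generation is deterministic for a fixed seed and respects quotas", {
  e1 <- suppressWarnings(generate_testsuite(fx$store, seed = 42))
  e2 <- suppressWarnings(generate_testsuite(fx$store, seed = 42))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_testsuite(e1, p1); write_testsuite(e2, p2)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical reruns
  # quota larger than eligible labels emits all eligible
  small <- suppressWarnings(generate_testsuite(fx$store, seed = 1,
                                               per_criterion_quota = 2))
  expect_true(all(table(small$criterion_id) <= 2 |
                    names(table(small$criterion_id)) == "coordination"))
  big <- suppressWarnings(generate_testsuite(fx$store, seed = 1,
                                             per_criterion_quota = 10000))
  n_len1 <- sum(big$criterion_id == "length_01")
  eligible1 <- sum(fx$lexicon$provenance == "LABEL" & fx$lexicon$token_count == 1)
  expect_lte(n_len1, eligible1)
  expect_gt(n_len1, 0)
})

test_that("curated families are skipped with a warning without input lists", {
  w <- capture_warnings(generate_testsuite(fx$store, seed = 1))
  expect_true(any(grepl("non_english", w)))
  expect_true(any(grepl("metaphoric", w)))
  cur <- list(metaphoric = tibble::tibble(input_text = "Bell-shaped thorax",
                                          concept_id = "HP:0001591"))
  e <- suppressWarnings(generate_testsuite(fx$store, seed = 1, curated = cur))
  m <- dplyr::filter(e, criterion_id == "metaphoric")
  expect_equal(m$input_text, "Bell-shaped thorax")
  expect_equal(m$expected[[1]]$concept_id, "HP:0001591")
})

test_that("synonym entries use the synonym surface with the parent concept", {
  e <- suppressWarnings(generate_testsuite(fx$store, seed = 7))
  syn <- dplyr::filter(e, criterion_id == "synonym")
  expect_gt(nrow(syn), 0)
  for (i in seq_len(nrow(syn))) {
    row <- dplyr::filter(fx$lexicon, surface == syn$input_text[i],
                         provenance == "SYNONYM")
    expect_equal(nrow(row), 1L, info = syn$input_text[i])
    expect_equal(syn$expected[[i]]$concept_id, row$concept_id)
  }
})

test_that("generator soundness: every entry is solvable by the oracle", {
  e <- suppressWarnings(generate_testsuite(fx$store, seed = 42))
  for (i in seq_len(nrow(e))) {
    expect_true(oracle_entry_solvable(e$input_text[i], e$expected[[i]]),
                info = e$input_text[i])
  }
  # and every entry carries a stratum
  expect_true(all(nzchar(e$category)))
})

test_that("mirror pairs are bijections over the same sampled concepts", {
  e <- suppressWarnings(generate_testsuite(fx$store, seed = 42))
  sing <- dplyr::filter(e, criterion_id == "singular")
  plur <- dplyr::filter(e, criterion_id == "plural")
  expect_equal(sing$concept_id, plur$concept_id)
  can <- dplyr::filter(e, criterion_id == "canonical_order")
  tra <- dplyr::filter(e, criterion_id == "canonical_order_transformed")
  expect_equal(can$concept_id, tra$concept_id)
  # transformed inputs really differ from the canonical ones
  expect_true(all(tra$input_text != can$input_text))
})

test_that("test suites round-trip through the TSV interchange format", {
  e <- suppressWarnings(generate_testsuite(fx$store, seed = 42))
  path <- withr::local_tempfile()
  write_testsuite(e, path)
  back <- read_testsuite(path)
  expect_equal(back$input_text, e$input_text)
  expect_equal(back$criterion_id, e$criterion_id)
  for (i in seq_len(nrow(e))) {
    expect_equal(back$expected[[i]], e$expected[[i]][names(back$expected[[i]])])
  }
})

test_that("suite runner scores echo and empty annotators correctly", {
  e <- suppressWarnings(generate_testsuite(fx$store, seed = 42,
                                           per_criterion_quota = 3))
  echo <- local({
    lookup <- e
    function(doc_id, text) {
      i <- match(text, lookup$input_text)
      dplyr::mutate(lookup$expected[[i]], doc_id = doc_id)
    }
  })
  res <- run_testsuite(e, echo)
  expect_equal(glance(res)$f_score, 1)
  expect_true(all(tidy(res)$f_score == 1))
  silent <- function(doc_id, text) tibble::tibble()
  res0 <- run_testsuite(e, silent)
  expect_equal(glance(res0)$recall, 0)
  expect_equal(glance(res0)$precision, 0)  # 0/0 convention
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("the recognizer solves transformed-order suites perfectly", {
  e <- suppressWarnings(generate_testsuite(fx$store, seed = 42))
  tra <- dplyr::filter(e, criterion_id == "canonical_order_transformed")
  res <- run_testsuite(tra, recognizer_annotator(fx$index))
  expect_equal(glance(res)$f_score, 1)
  # with order-invariant matching off the mirror breaks
  res_off <- run_testsuite(
    tra, recognizer_annotator(fx$index,
                              recognizer_options(order_invariant = FALSE)))
  expect_lt(glance(res_off)$f_score, 1)
})
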