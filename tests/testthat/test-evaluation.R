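test_that("gold corpus round-trips through the standoff dialect", {
  dir <- withr::local_tempdir()
  gold <- fixture_gold_corpus()
  write_gold(gold, dir)
  back <- read_gold(dir)
  expect_equal(back$documents, gold$documents)
  expect_equal(back$annotations, gold$annotations)
  # a span annotated with two concepts appears as two instances
  gs02 <- dplyr::filter(back$annotations, doc_id == "gs_02")
  expect_equal(nrow(gs02), 2L)
  expect_equal(length(unique(gs02$start)), 1L)
})

test_that("offset/text mismatches are rejected citing document and line", {
  dir <- withr::local_tempdir()
  cat("Both patients had hypoplastic nails.",
      file = file.path(dir, "d1.txt"))
  writeLines("0\t4\twrong\tHP:0200002", file.path(dir, "d1.ann"))
  expect_error(read_gold(dir), "d1.ann line 1")
})

test_that("unknown-shaped concept ids are kept with a warning", {
  dir <- withr::local_tempdir()
  cat("hypoplastic nails", file = file.path(dir, "d1.txt"))
  writeLines("0\t17\thypoplastic nails\tNOT_A_CURIE", file.path(dir, "d1.ann"))
  expect_warning(gold <- read_gold(dir), "NOT_A_CURIE")
  expect_equal(nrow(gold$annotations), 1L)
})

test_that("alignment requires exact boundaries and concept identity", {
  gold <- tibble::tibble(doc_id = "d", start = 10L, end = 36L,
                         matched_text = "x", concept_id = "HP:0200002")
  expect_equal(align_annotations(gold, gold),
               tibble::tibble(TP = 1L, FP = 0L, FN = 0L))
  off_by_one <- dplyr::mutate(gold, start = start + 1L)
  expect_equal(align_annotations(gold, off_by_one),
               tibble::tibble(TP = 0L, FP = 1L, FN = 1L))
  # tail-only coordination match: prediction nested in the gold span
  gold2 <- tibble::tibble(doc_id = "d", start = 0L, end = 29L,
                          concept_id = "HP:0200002")
  pred2 <- tibble::tibble(doc_id = "d", start = 12L, end = 29L,
                          concept_id = "HP:0200002")
  expect_equal(align_annotations(gold2, pred2),
               tibble::tibble(TP = 0L, FP = 1L, FN = 1L))
  # duplicate identical predictions deduplicate before alignment
  expect_equal(align_annotations(gold, dplyr::bind_rows(gold, gold)),
               tibble::tibble(TP = 1L, FP = 0L, FN = 0L))
})

test_that("precision/recall/F formulas and 0/0 conventions hold", {
  r <- prf(9, 4, 14)
  expect_equal(r$precision, 9 / 13)
  expect_equal(r$recall, 9 / 23)
  expect_equal(r$f_score, 2 * (9 / 13) * (9 / 23) / (9 / 13 + 9 / 23))
  expect_equal(r$f_score, 0.5)
  expect_equal(unlist(prf(0, 0, 0)), c(precision = 0, recall = 0, f_score = 0))
  expect_equal(prf(0, 5, 0)$precision, 0)
  expect_equal(prf(0, 0, 5)$f_score, 0)
})

test_that("F is bounded by max(P, R) and equals them when P == R", {
  withr::with_seed(5, {
    for (i in 1:50) {
      tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
      r <- prf(tp, fp, fn)
      expect_lte(r$f_score, max(r$precision, r$recall) + 1e-12)
      expect_gte(r$f_score, 0)
    }
  })
  r <- prf(6, 3, 3)
  expect_equal(r$precision, r$recall)
  expect_equal(r$f_score, r$precision)
})

test_that("alignment equals the brute-force bipartite oracle on random docs", {
  ids <- fx$store$concepts$id
  withr::with_seed(17, {
    for (rep in 1:25) {
      n_g <- sample(0:20, 1)
      n_p <- sample(0:20, 1)
      mk <- function(n) {
        if (!n) {
          return(tibble::tibble(doc_id = character(), start = integer(),
                                end = integer(), concept_id = character()))
        }
        s <- sample(0:30, n, replace = TRUE)
        tibble::tibble(doc_id = sample(c("d1", "d2"), n, replace = TRUE),
                       start = s, end = s + sample(1:10, n, replace = TRUE),
                       concept_id = sample(ids, n, replace = TRUE))
      }
      gold <- mk(n_g)
      pred <- mk(n_p)
      got <- align_annotations(gold, pred)
      want <- oracle_align(gold, dplyr::distinct(pred))
      expect_equal(c(TP = got$TP, FP = got$FP, FN = got$FN), want)
      # conservation (predictions deduplicated by contract)
      pu <- nrow(dplyr::distinct(pred, doc_id, start, end, concept_id))
      expect_equal(got$TP + got$FN, nrow(gold))
      expect_equal(got$TP + got$FP, pu)
    }
  })
})

test_that("corpus evaluation stratifies by top-level category", {
  gold <- fixture_gold_corpus()
  pred <- annotate_corpus(gold$documents, fx$index)
  ev <- evaluate_corpus(gold, pred, fx$cmap)
  g <- glance(ev)
  expect_equal(g$TP + g$FN, nrow(gold$annotations))
  strata <- tidy(ev)
  # a multi-parent concept contributes to each of its categories
  gold250 <- new_gold <- gold
  gold250$annotations <- tibble::tibble(
    doc_id = "gs_01", start = 0L, end = 4L, matched_text = "Both",
    concept_id = "HP:0000250")
  ev250 <- evaluate_corpus(gold250, gold250$annotations, fx$cmap)
  s250 <- tidy(ev250)
  expect_setequal(s250$stratum[s250$TP > 0], c("HP:0000152", "HP:0000924"))
  # single-category corpus collapses to the overall scores
  gold1 <- gold
  gold1$annotations <- dplyr::filter(gold$annotations, doc_id == "gs_01")
  gold1$documents <- dplyr::filter(gold$documents, doc_id == "gs_01")
  pred1 <- dplyr::filter(pred, doc_id == "gs_01")
  ev1 <- evaluate_corpus(gold1, pred1, fx$cmap)
  expect_equal(nrow(tidy(ev1)), 1L)
  expect_equal(tidy(ev1)$f_score, glance(ev1)$f_score)
  # concepts outside the root subtree land in "uncategorized"
  goldu <- gold1
  goldu$annotations$concept_id <- "HP:0000001"
  evu <- evaluate_corpus(goldu, goldu$annotations, fx$cmap)
  expect_true("uncategorized" %in% tidy(evu)$stratum)
})

test_that("tidiers, glance and autoplot work on evaluation reports", {
  gold <- fixture_gold_corpus()
  pred <- annotate_corpus(gold$documents, fx$index)
  ev <- evaluate_corpus(gold, pred, fx$cmap)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1L)
  p <- ggplot2::autoplot(ev)
  expect_s3_class(p, "ggplot")
})

test_that("half-up rounding matches printed two-decimal presentation", {
  expect_equal(round_half_up(0.345), 0.35)
  expect_equal(round_half_up(0.3449), 0.34)
  expect_equal(round_half_up(0.5, 0), 1)
})
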