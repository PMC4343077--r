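#' Gold corpus container and standoff reader/writer
#'
#' A gold corpus pairs document texts with gold annotation instances in a
#' simple standoff dialect: for every `<doc_id>.txt` a `<doc_id>.ann` TSV
#' with one instance per line — `start TAB end TAB text TAB concept_id`,
#' 0-based half-open character offsets.  A span annotated with k concepts
#' appears on k lines.  `read_gold()` validates that every annotation's
#' text slice matches the document and errors citing the document and
#' line otherwise; an annotation whose concept id has an unexpected shape
#' is kept with a warning.
#'
#' @param dir Directory containing `*.txt` / `*.ann` pairs.
#' @param id_pattern Expected concept id shape (warning only).
#' @return A `gold_corpus`: list of tibbles `documents` (`doc_id`,
#'   `text`) and `annotations` (`doc_id`, `start`, `end`, `matched_text`,
#'   `concept_id`).
#' @export
read_gold <- function(dir, id_pattern = "^[A-Za-z]+:\\d{7}$") {
  stopifnot(dir.exists(dir))
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) stop("no .txt documents under ", dir)
  docs <- tibble(
    doc_id = sub("\\.txt$", "", basename(txts)),
    text = vapply(txts, function(f) {
      readChar(f, file.info(f)$size, useBytes = FALSE)
    }, character(1), USE.NAMES = FALSE)
  )
  anns <- lapply(seq_len(nrow(docs)), function(i) {
    f <- file.path(dir, paste0(docs$doc_id[i], ".ann"))
    if (!file.exists(f) || file.info(f)$size == 0) return(NULL)
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(NULL)
    parts <- str_split(lines, "\t")
    bad <- which(lengths(parts) != 4L)
    if (length(bad)) {
      stop("malformed annotation in ", basename(f), " line ", bad[1])
    }
    out <- tibble(
      doc_id = docs$doc_id[i],
      start = as.integer(map_chr(parts, 1)),
      end = as.integer(map_chr(parts, 2)),
      matched_text = map_chr(parts, 3),
      concept_id = map_chr(parts, 4)
    )
    slice <- substring(docs$text[i], out$start + 1L, out$end)
    mism <- which(slice != out$matched_text)
    if (length(mism)) {
      stop("offset/text mismatch in ", basename(f), " line ", mism[1],
           ": expected ", dQuote(out$matched_text[mism[1]]),
           ", document has ", dQuote(slice[mism[1]]))
    }
    unk <- which(!grepl(id_pattern, out$concept_id))
    if (length(unk)) {
      warning("concept id(s) with unexpected shape in ", basename(f), ": ",
              paste(unique(out$concept_id[unk]), collapse = ", "),
              " (kept)", call. = FALSE)
    }
    out
  })
  ann <- bind_rows(anns)
  if (is.null(ann) || !nrow(ann)) {
    ann <- tibble(doc_id = character(), start = integer(), end = integer(),
                  matched_text = character(), concept_id = character())
  }
  new_gold_corpus(docs, arrange(ann, .data$doc_id, .data$start, .data$end,
                                .data$concept_id))
}

new_gold_corpus <- function(documents, annotations) {
  structure(list(documents = as_tibble(documents),
                 annotations = as_tibble(annotations)),
            class = "gold_corpus")
}

#' @export
print.gold_corpus <- function(x, ...) {
  cat("<gold_corpus> ", nrow(x$documents), " documents, ",
      nrow(x$annotations), " gold annotation instances\n", sep = "")
  invisible(x)
}

#' @rdname read_gold
#' @param corpus A `gold_corpus`.
#' @export
write_gold <- function(corpus, dir) {
  stopifnot(inherits(corpus, "gold_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus$documents))) {
    d <- corpus$documents$doc_id[i]
    cat(corpus$documents$text[i], file = file.path(dir, paste0(d, ".txt")))
    ann <- corpus$annotations[corpus$annotations$doc_id == d, ]
    lines <- sprintf("%d\t%d\t%s\t%s", ann$start, ann$end,
                     ann$matched_text, ann$concept_id)
    writeLines(lines, file.path(dir, paste0(d, ".ann")))
  }
  invisible(corpus)
}

#' Align predictions to gold with exact boundary matching
#'
#' An annotation instance matches iff `start`, `end` and `concept_id` are
#' all equal (within the same document); each instance is matched at most
#' once.  There is no partial or overlap credit — a prediction off by one
#' character counts as one false positive plus one false negative.
#' Identical duplicate predictions are deduplicated before alignment.
#'
#' @param gold,predicted Annotation tibbles (columns `doc_id`, `start`,
#'   `end`, `concept_id`).
#' @return One-row tibble with `TP`, `FP`, `FN`.
#' @export
align_annotations <- function(gold, predicted) {
  key <- function(x) {
    if (!nrow(x)) return(character(0))
    paste(x$doc_id, x$start, x$end, x$concept_id, sep = "\r")
  }
  g <- key(gold)
  p <- unique(key(predicted))
  gt <- table(g)
  pt <- table(p)
  common <- intersect(names(gt), names(pt))
  tp <- sum(pmin(as.integer(gt[common]), as.integer(pt[common])))
  tibble(TP = as.integer(tp),
         FP = as.integer(length(p) - tp),
         FN = as.integer(length(g) - tp))
}

#' Precision, recall and F-score
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`, with the 0/0
#' conventions `P = 0` when `TP+FP = 0`, `R = 0` when `TP+FN = 0` and
#' `F = 0` when `P+R = 0`.
#'
#' @param tp Either a numeric vector of true-positive counts, or a data
#'   frame with columns `TP`, `FP`, `FN` (then `fp`/`fn` are ignored).
#' @param fp,fn False positive / false negative counts.
#' @return Tibble with columns `precision`, `recall`, `f_score`.
#' @export
#' @examples
#' prf(9, 4, 14)
prf <- function(tp, fp = NULL, fn = NULL) {
  if (is.data.frame(tp)) {
    fp <- tp$FP
    fn <- tp$FN
    tp <- tp$TP
  }
  p <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  r <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  tibble(precision = p, recall = r, f_score = f)
}

#' Round half up at a fixed number of decimals
#'
#' Presentation-layer rounding (2 decimals, half up) used when printing
#' scores; all internal computation stays at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Evaluate predictions against a gold corpus
#'
#' Exact-boundary alignment per document, pooled corpus-wide counts, and
#' (when a [assign_categories()] map is supplied) independent
#' per-top-level-category scores.  Each instance contributes to every
#' category of its concept, so a multi-parent concept such as *Dense
#' calvaria* is counted once per category; per-stratum counts therefore
#' need not sum to the overall counts.  Instances whose concept falls
#' outside the category root's subtree land in an `"uncategorized"`
#' stratum.
#'
#' @param gold A `gold_corpus` from [read_gold()] or
#'   [fixture_gold_corpus()].
#' @param predicted Annotation tibble (e.g. from [annotate_corpus()]).
#' @param category_map Optional `category_map` for stratification.
#' @return A `cr_eval` object; see [tidy.cr_eval()], [glance.cr_eval()],
#'   [autoplot.cr_eval()].
#' @export
#' @examples
#' store <- fixture_concept_store()
#' index <- build_index(build_lexicon(store), store)
#' gold <- fixture_gold_corpus()
#' pred <- annotate_corpus(gold$documents, index)
#' glance(evaluate_corpus(gold, pred))
evaluate_corpus <- function(gold, predicted, category_map = NULL) {
  stopifnot(inherits(gold, "gold_corpus"))
  gold_ann <- gold$annotations
  pred <- distinct(as_tibble(predicted),
                   .data$doc_id, .data$start, .data$end, .data$concept_id)
  per_document <- bind_rows(lapply(gold$documents$doc_id, function(d) {
    cbind(tibble(doc_id = d),
          align_annotations(gold_ann[gold_ann$doc_id == d, ],
                            pred[pred$doc_id == d, ]))
  }))
  # predictions for unknown documents are corpus-level false positives
  stray <- pred[!pred$doc_id %in% gold$documents$doc_id, ]
  overall <- tibble(TP = sum(per_document$TP),
                    FP = sum(per_document$FP) + nrow(stray),
                    FN = sum(per_document$FN))
  per_stratum <- NULL
  if (!is.null(category_map)) {
    stopifnot(inherits(category_map, "category_map"))
    strata_of <- function(x) {
      if (!nrow(x)) {
        return(mutate(x, stratum = character(0)))
      }
      x |>
        left_join(rename(category_map$map, stratum = "category"),
                  by = c(concept_id = "concept_id"),
                  relationship = "many-to-many") |>
        mutate(stratum = ifelse(is.na(.data$stratum), "uncategorized",
                                .data$stratum))
    }
    gs <- strata_of(gold_ann)
    ps <- strata_of(pred)
    strata <- sort(unique(c(gs$stratum, ps$stratum)), method = "radix")
    per_stratum <- bind_rows(lapply(strata, function(s) {
      counts <- align_annotations(gs[gs$stratum == s, ], ps[ps$stratum == s, ])
      cbind(tibble(stratum = s), counts, prf(counts))
    }))
    per_stratum <- left_join(
      per_stratum,
      rename(category_map$categories, stratum = "id", stratum_label = "label"),
      by = "stratum"
    )
  }
  structure(
    list(overall = cbind(overall, prf(overall)),
         per_document = per_document,
         per_stratum = per_stratum,
         n_gold = nrow(gold_ann),
         n_predicted = nrow(pred)),
    class = "cr_eval"
  )
}

#' @export
print.cr_eval <- function(x, ...) {
  o <- x$overall
  cat("<cr_eval> exact-boundary matching\n")
  cat(sprintf("  TP %d  FP %d  FN %d\n", o$TP, o$FP, o$FN))
  cat(sprintf("  P %.2f  R %.2f  F %.2f\n",
              round_half_up(o$precision), round_half_up(o$recall),
              round_half_up(o$f_score)))
  if (!is.null(x$per_stratum)) {
    cat("  strata: ", nrow(x$per_stratum), " top-level categories\n", sep = "")
  }
  invisible(x)
}

#' Tidiers and plot for evaluation reports
#'
#' `tidy()` returns one row per stratum (or per document when the report
#' is unstratified); `glance()` returns the one-row overall summary;
#' `autoplot()` draws per-stratum F-scores.
#'
#' @param x A `cr_eval` object.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @export
tidy.cr_eval <- function(x, ...) {
  if (!is.null(x$per_stratum)) {
    return(as_tibble(x$per_stratum))
  }
  as_tibble(cbind(x$per_document, prf(x$per_document)))
}

#' @rdname tidy.cr_eval
#' @export
glance.cr_eval <- function(x, ...) {
  as_tibble(x$overall)
}

#' @rdname tidy.cr_eval
#' @param object A `cr_eval` object.
#' @export
autoplot.cr_eval <- function(object, ...) {
  d <- tidy(object)
  if (is.null(object$per_stratum)) {
    d$stratum <- d$doc_id
  } else if (!is.null(d$stratum_label)) {
    d$stratum <- ifelse(is.na(d$stratum_label), d$stratum, d$stratum_label)
  }
  ggplot(d, aes(x = stats::reorder(.data$stratum, .data$f_score),
                y = .data$f_score)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = glance(object)$f_score, linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = "F-score (exact boundary)",
         title = "Concept recognition F-score by stratum",
         subtitle = "dashed line: overall") +
    theme_minimal()
}
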