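#' Recognizer options
#'
#' @param order_invariant Match token windows by order-free signature
#'   equality in addition to exact normalized sequences (default on).
#' @param coordination Decompose coordinated mentions
#'   ("short and broad fingers") into their atomic concepts (default on).
#' @param non_canonical Rewrite verbal phenotype clauses
#'   ("fingers are short and broad") to canonical quality-entity form and
#'   match those too (default off).
#' @param max_window_tokens Longest token window scanned; HPO label
#'   lengths range from 1 to 14 tokens, hence the default.
#' @param ambiguous When one signature maps to several concepts:
#'   `"all"` emits every candidate (overlap resolution tie-breaks later);
#'   `"none"` is a strict mode that emits no annotation for the window.
#' @return A list of class `recognizer_options`.
#' @export
recognizer_options <- function(order_invariant = TRUE,
                               coordination = TRUE,
                               non_canonical = FALSE,
                               max_window_tokens = 14L,
                               ambiguous = c("all", "none")) {
  stopifnot(max_window_tokens >= 1)
  structure(
    list(
      order_invariant = isTRUE(order_invariant),
      coordination = isTRUE(coordination),
      non_canonical = isTRUE(non_canonical),
      max_window_tokens = as.integer(max_window_tokens),
      ambiguous = match.arg(ambiguous)
    ),
    class = "recognizer_options"
  )
}

empty_annotations <- function() {
  tibble(doc_id = character(), start = integer(), end = integer(),
         matched_text = character(), concept_id = character(),
         match_type = character())
}

ann_row <- function(doc_id, text, start, end, ids, match_type) {
  if (!length(ids)) return(NULL)
  tibble(doc_id = doc_id, start = start, end = end,
         matched_text = substr(text, start + 1L, end),
         concept_id = ids, match_type = match_type)
}

# Verb-ish tokens that bound coordination regions and anchor the
# non-canonical rewrite.  A shallow, deliberately small list.
COPULAS <- c("is", "are", "was", "were", "be", "been", "appear", "appears",
             "appeared", "remain", "remains", "remained", "become",
             "becomes", "became", "seem", "seems", "seemed")
REGION_STOPS <- c(COPULAS, "has", "had", "have", "having", "show", "shows",
                  "showed", "shown", "reveal", "reveals", "revealed",
                  "present", "presents", "presented", "presenting", "note",
                  "noted", "observe", "observed", "display", "displayed",
                  "exhibit", "exhibited", "find", "found", "diagnose",
                  "diagnosed", "characterise", "characterised",
                  "characterize", "characterized", "include", "includes",
                  "included", "including", "and/or")

#' Annotate one document
#'
#' The concept-recognition engine.  A greedy left-to-right scan matches
#' token windows (longest first, up to `max_window_tokens`) against the
#' index: first by exact normalized token sequence (`EXACT_SURFACE`), then
#' — when enabled — by order-free signature (`ORDER_INVARIANT`).  A
#' coordination pass decomposes conjunct lists joined by commas, "and" or
#' "or" (`COORDINATION`), a non-canonical pass rewrites simple verbal
#' clauses (`NON_CANONICAL`), and all candidates are then passed through
#' [resolve_overlaps()].  Negated mentions are annotated like any others;
#' negation handling is deliberately left to downstream consumers.
#'
#' Offsets are 0-based, half-open, character-based throughout, so
#' `substr(text, start + 1, end) == matched_text`.
#'
#' @param text Document text (single string).
#' @param index A [build_index()] object.
#' @param doc_id Document identifier recorded in the output.
#' @param options A [recognizer_options()].
#' @return Annotation tibble: `doc_id`, `start`, `end`, `matched_text`,
#'   `concept_id`, `match_type`, sorted by (`start`, `end`,
#'   `concept_id`).  One span may carry several concept instances.
#' @export
#' @examples
#' index <- build_index(build_lexicon(fixture_concept_store()),
#'                      fixture_concept_store())
#' annotate_text("no kidney anomalies were found", index)
annotate_text <- function(text, index, doc_id = "doc",
                          options = recognizer_options()) {
  stopifnot(inherits(index, "cr_index"))
  if (is.na(text) || !nzchar(text)) return(empty_annotations())
  config <- index$config
  tokens <- tokenize(text, config)
  if (!nrow(tokens)) return(empty_annotations())
  cands <- list(main_scan(doc_id, text, tokens, index, options))
  if (options$coordination) {
    cands <- c(cands, list(coordination_pass(doc_id, text, tokens, index, options)))
  }
  if (options$non_canonical) {
    cands <- c(cands, list(non_canonical_pass(doc_id, text, tokens, index, options)))
  }
  out <- bind_rows(cands)
  if (!nrow(out)) return(empty_annotations())
  resolve_overlaps(out, index$store)
}

#' Annotate a corpus of documents
#'
#' Data-frame-first wrapper over [annotate_text()]: takes a tibble of
#' documents, returns one tibble of annotations, so corpus annotation
#' chains with the pipe.
#'
#' @param docs Tibble with columns `doc_id` and `text`.
#' @inheritParams annotate_text
#' @return Annotation tibble (see [annotate_text()]).
#' @export
#' @examples
#' corpus <- fixture_gold_corpus()
#' index <- build_index(build_lexicon(fixture_concept_store()),
#'                      fixture_concept_store())
#' annotate_corpus(corpus$documents, index)
annotate_corpus <- function(docs, index, options = recognizer_options()) {
  stopifnot(is.data.frame(docs), all(c("doc_id", "text") %in% names(docs)))
  out <- purrr::map2(docs$doc_id, docs$text,
                     function(d, x) annotate_text(x, index, doc_id = d,
                                                  options = options))
  out <- bind_rows(out)
  if (!nrow(out)) empty_annotations() else out
}

# ---- main dictionary scan ------------------------------------------------

# Runs of word tokens unbroken by punctuation; windows never cross
# punctuation and must start and end on a content (non stop-word) token.
token_runs <- function(tokens) {
  idx <- which(!tokens$punct)
  if (!length(idx)) return(list())
  brk <- c(TRUE, diff(idx) > 1)  # any gap in indices is punctuation
  unname(split(idx, cumsum(brk)))
}

main_scan <- function(doc_id, text, tokens, index, options) {
  out <- list()
  for (run in token_runs(tokens)) {
    m <- length(run)
    i <- 1L
    while (i <= m) {
      ti <- run[i]
      if (tokens$stopword[ti]) { i <- i + 1L; next }
      hit_len <- 0L
      hit_exact <- character(0)
      hit_sig <- character(0)
      for (len in seq(min(options$max_window_tokens, m - i + 1L), 1L)) {
        tj <- run[i + len - 1L]
        if (tokens$stopword[tj]) next
        w <- run[i:(i + len - 1L)]
        norms <- tokens$norm[w]
        exact_ids <- index_exact_ids(index, paste(norms, collapse = " "))
        sig_ids <- if (options$order_invariant) {
          setdiff(resolve_norms(index, norms), exact_ids)
        } else {
          character(0)
        }
        if (length(exact_ids) || length(sig_ids)) {
          if (length(exact_ids) + length(sig_ids) > 1 &&
              options$ambiguous == "none") {
            break
          }
          hit_len <- len
          hit_exact <- exact_ids
          hit_sig <- sig_ids
          break
        }
      }
      if (hit_len > 0L) {
        tj <- run[i + hit_len - 1L]
        out[[length(out) + 1L]] <- ann_row(doc_id, text, tokens$start[ti],
                                           tokens$end[tj], hit_exact,
                                           "EXACT_SURFACE")
        out[[length(out) + 1L]] <- ann_row(doc_id, text, tokens$start[ti],
                                           tokens$end[tj], hit_sig,
                                           "ORDER_INVARIANT")
        i <- i + hit_len
      } else {
        i <- i + 1L
      }
    }
  }
  res <- bind_rows(out)
  if (is.null(res) || !nrow(res)) empty_annotations() else res
}

# ---- sentences -----------------------------------------------------------

# Sentence id per token: boundary after ., ? or ! when followed by a
# capitalized word token (or end of document).
sentence_ids <- function(tokens, text) {
  n <- nrow(tokens)
  sid <- integer(n)
  cur <- 1L
  for (k in seq_len(n)) {
    sid[k] <- cur
    if (tokens$punct[k] && tokens$text[k] %in% c(".", "?", "!")) {
      nxt <- if (k < n) which(!tokens$punct[(k + 1):n])[1] + k else NA_integer_
      if (is.na(nxt) || grepl("^[A-Z]", tokens$text[nxt])) cur <- cur + 1L
    }
  }
  sid
}

# ---- coordination decomposition -----------------------------------------

#' Decompose coordinated phenotype mentions
#'
#' Finds conjunct lists joined by commas, "and" or "or" within a sentence
#' and resolves each (shared-part + conjunct) combination against the
#' index.  Two output shapes, mirroring the gold-standard guidelines:
#'
#' * qualifier *preceding* the conjunction (or a shared plain entity head
#'   following it) — one full-span annotation per resolved conjunct, all
#'   on the whole phrase ("synostosis of some carpal and tarsal bones",
#'   "short and broad fingers");
#' * qualifier (a quality noun such as "malformations") *succeeding* the
#'   conjunction — nested suffix spans, one from each conjunct's start to
#'   the qualifier's end ("branchial arch, otic and renal
#'   malformations").
#'
#' Conjuncts that resolve to no concept are skipped; a decomposition is
#' emitted only when at least two conjuncts resolve.  Mixed patterns with
#' resolvable material on both sides are treated as qualifier-preceding.
#'
#' @param text Sentence or document text.
#' @inheritParams annotate_text
#' @return Annotation tibble with `match_type = "COORDINATION"`.
#' @export
decompose_coordination <- function(text, index, doc_id = "doc",
                                   options = recognizer_options()) {
  stopifnot(inherits(index, "cr_index"))
  if (is.na(text) || !nzchar(text)) return(empty_annotations())
  tokens <- tokenize(text, index$config)
  coordination_pass(doc_id, text, tokens, index, options)
}

coordination_pass <- function(doc_id, text, tokens, index, options) {
  config <- index$config
  n <- nrow(tokens)
  if (!n) return(empty_annotations())
  sid <- sentence_ids(tokens, text)
  out <- list()
  for (s in unique(sid)) {
    idx <- which(sid == s)
    coords <- idx[!tokens$punct[idx] & tokens$norm[idx] %in% c("and", "or")]
    if (!length(coords)) next
    # tokens that terminate a region: sentence punctuation other than the
    # comma, and verb-ish boundary tokens
    stops <- idx[(tokens$punct[idx] & tokens$text[idx] != ",") |
                   (!tokens$punct[idx] & tokens$norm[idx] %in% REGION_STOPS)]
    blocks <- split(idx[!idx %in% stops],
                    cumsum(idx %in% stops)[!idx %in% stops])
    for (region in blocks) {
      if (!any(coords %in% region)) next
      out[[length(out) + 1L]] <-
        decompose_region(doc_id, text, tokens, region, index, options)
    }
  }
  res <- bind_rows(out)
  if (is.null(res) || !nrow(res)) empty_annotations() else res
}

decompose_region <- function(doc_id, text, tokens, region, index, options) {
  config <- index$config
  seps <- region[(tokens$punct[region] & tokens$text[region] == ",") |
                   (!tokens$punct[region] & tokens$norm[region] %in% c("and", "or"))]
  items <- split(region[!region %in% seps],
                 cumsum(region %in% seps)[!region %in% seps])
  items <- unname(items[lengths(items) > 0])
  if (length(items) < 2) return(NULL)
  first <- items[[1]]
  last <- items[[length(items)]]
  middle <- if (length(items) > 2) items[2:(length(items) - 1)] else list()
  content <- function(w) w[!tokens$stopword[w]]
  resolve_ids <- function(w) {
    ids <- resolve_norms(index, tokens$norm[w])
    if (length(ids) > 1 && options$ambiguous == "none") character(0) else ids
  }

  best <- NULL
  for (p in 0:(length(first) - 1L)) {
    for (s in 0:(length(last) - 1L)) {
      Q <- if (p > 0) first[seq_len(p)] else integer(0)
      X1 <- first[setdiff(seq_along(first), seq_len(p))]
      Xk <- last[seq_len(length(last) - s)]
      Tt <- if (s > 0) last[seq(length(last) - s + 1L, length(last))] else integer(0)
      # a true coordination shares material with every conjunct; without a
      # shared qualifier or head this is just adjacent independent mentions
      if (!length(content(Q)) && !length(content(Tt))) next
      conj <- c(list(X1), middle, list(Xk))
      conj <- conj[vapply(conj, function(w) length(content(w)) > 0, logical(1))]
      if (length(conj) < 2) next
      ids <- lapply(conj, function(w) resolve_ids(c(Q, w, Tt)))
      score <- sum(lengths(ids) > 0)
      if (score < 2) next
      cand <- list(p = p, s = s, Q = Q, Tt = Tt, conj = conj, ids = ids,
                   score = score)
      if (is.null(best) ||
          score > best$score ||
          (score == best$score && (p + s) < (best$p + best$s))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)

  q_content <- length(content(best$Q)) > 0
  t_content <- content(best$Tt)
  tail_head <- if (length(t_content)) tokens$norm[t_content[length(t_content)]] else NA
  case_b <- !q_content && !is.na(tail_head) && tail_head %in% config$quality_nouns

  resolved <- which(lengths(best$ids) > 0)
  rows <- list()
  if (case_b) {
    for (k in resolved) {
      span_tok <- content(c(best$conj[[k]], best$Tt))
      rows[[length(rows) + 1L]] <- ann_row(
        doc_id, text,
        tokens$start[span_tok[1]], tokens$end[span_tok[length(span_tok)]],
        best$ids[[k]], "COORDINATION"
      )
    }
  } else {
    span_tok <- content(c(best$Q, unlist(best$conj), best$Tt))
    span_tok <- sort(span_tok)
    st <- tokens$start[span_tok[1]]
    en <- tokens$end[span_tok[length(span_tok)]]
    for (k in resolved) {
      rows[[length(rows) + 1L]] <- ann_row(doc_id, text, st, en,
                                           best$ids[[k]], "COORDINATION")
    }
  }
  bind_rows(rows)
}

# ---- non-canonical phenotypes -------------------------------------------

#' Match non-canonical (verbal) phenotype clauses
#'
#' A small registry of shallow patterns: `ENTITY copula QUALIFIER(-list)`
#' and `ENTITY verb QUALIFIER`.  Each qualifier is rewritten to canonical
#' `QUALIFIER ENTITY` form and resolved through the index; the emitted
#' span covers the matched clause.  "fingers are short and broad" thus
#' aligns to the same concepts as "short and broad fingers".
#'
#' @inheritParams decompose_coordination
#' @return Annotation tibble with `match_type = "NON_CANONICAL"`.
#' @export
match_non_canonical <- function(text, index, doc_id = "doc",
                                options = recognizer_options()) {
  stopifnot(inherits(index, "cr_index"))
  if (is.na(text) || !nzchar(text)) return(empty_annotations())
  tokens <- tokenize(text, index$config)
  non_canonical_pass(doc_id, text, tokens, index, options)
}

non_canonical_pass <- function(doc_id, text, tokens, index, options) {
  n <- nrow(tokens)
  if (!n) return(empty_annotations())
  sid <- sentence_ids(tokens, text)
  out <- list()
  for (v in which(!tokens$punct & tokens$norm %in% COPULAS)) {
    s <- sid[v]
    left <- which(sid == s & seq_len(n) < v & !tokens$punct)
    # entity: maximal run of content tokens immediately left of the verb
    ent <- integer(0)
    k <- length(left)
    while (k >= 1 && !tokens$stopword[left[k]] &&
           !tokens$norm[left[k]] %in% REGION_STOPS &&
           left[k] == v - (length(ent) + 1L)) {
      ent <- c(left[k], ent)
      k <- k - 1L
    }
    if (!length(ent)) next
    # qualifier list: content tokens right of the verb, split on and/or/comma
    right <- integer(0)
    j <- v + 1L
    while (j <= n && sid[j] == s &&
           ((tokens$punct[j] && tokens$text[j] == ",") ||
              (!tokens$punct[j] && !tokens$norm[j] %in% REGION_STOPS))) {
      right <- c(right, j)
      j <- j + 1L
    }
    if (!length(right)) next
    is_sep <- (tokens$punct[right] & tokens$text[right] == ",") |
      (!tokens$punct[right] & tokens$norm[right] %in% c("and", "or"))
    quals <- split(right[!is_sep], cumsum(is_sep)[!is_sep])
    quals <- unname(quals[lengths(quals) > 0])
    if (!length(quals)) next
    ids <- lapply(quals, function(q) {
      r <- resolve_norms(index, c(tokens$norm[q], tokens$norm[ent]))
      if (length(r) > 1 && options$ambiguous == "none") character(0) else r
    })
    resolved <- which(lengths(ids) > 0)
    if (!length(resolved)) next
    last_q <- max(unlist(quals[resolved]))
    for (k in resolved) {
      out[[length(out) + 1L]] <- ann_row(
        doc_id, text, tokens$start[ent[1]], tokens$end[last_q],
        ids[[k]], "NON_CANONICAL"
      )
    }
  }
  res <- bind_rows(out)
  if (is.null(res) || !nrow(res)) empty_annotations() else res
}

# ---- overlap resolution --------------------------------------------------

#' Resolve overlapping candidate annotations
#'
#' Among overlapping candidates whose concepts are hierarchically related
#' (identical, or ancestor/descendant), the longer span wins; on identical
#' spans the more specific (deeper) concept wins, with the lexicographic
#' CURIE as the final tie-break.  Hierarchically unrelated concepts on
#' overlapping or identical spans are all kept — multi-annotation of one
#' span is intentional.  Nested suffix spans produced by coordination
#' decomposition (`match_type == "COORDINATION"`) are exempt from
#' suppression.  Exact duplicates (same span, same concept) are collapsed
#' first, preferring the coordination-tagged instance.
#'
#' @param annotations Annotation tibble (candidates).
#' @param store The [concept_store()] providing the hierarchy.
#' @return Annotation tibble sorted by (`doc_id`, `start`, `end`,
#'   `concept_id`).
#' @export
resolve_overlaps <- function(annotations, store) {
  stopifnot(inherits(store, "concept_store"))
  if (!nrow(annotations)) return(empty_annotations())
  type_rank <- c(COORDINATION = 1L, EXACT_SURFACE = 2L, ORDER_INVARIANT = 3L,
                 NON_CANONICAL = 4L)
  a <- annotations |>
    mutate(.rank = type_rank[.data$match_type]) |>
    arrange(.data$doc_id, .data$start, .data$end, .data$concept_id, .data$.rank) |>
    distinct(.data$doc_id, .data$start, .data$end, .data$concept_id,
             .keep_all = TRUE)

  anc <- new.env(parent = emptyenv())
  anc_of <- function(id) {
    got <- get0(id, envir = anc)
    if (is.null(got)) {
      got <- if (id %in% store$concepts$id) ancestors(store, id) else character(0)
      assign(id, got, envir = anc)
    }
    got
  }
  depths <- concept_depths(store)
  depth_of <- function(id) {
    d <- depths[id]
    if (is.na(d)) -1L else unname(d)
  }
  related <- function(x, y) {
    x == y || x %in% anc_of(y) || y %in% anc_of(x)
  }

  keep <- rep(TRUE, nrow(a))
  for (d in unique(a$doc_id)) {
    ii <- which(a$doc_id == d)
    if (length(ii) < 2) next
    for (u in seq_along(ii)[-length(ii)]) {
      for (w in seq(u + 1L, length(ii))) {
        i <- ii[u]; j <- ii[w]
        if (!keep[i] || !keep[j]) next
        if (a$start[i] >= a$end[j] || a$start[j] >= a$end[i]) next  # disjoint
        if (!related(a$concept_id[i], a$concept_id[j])) next
        li <- a$end[i] - a$start[i]
        lj <- a$end[j] - a$start[j]
        victim <- if (li != lj) {
          if (li < lj) i else j
        } else {
          di <- depth_of(a$concept_id[i])
          dj <- depth_of(a$concept_id[j])
          if (di != dj) {
            if (di < dj) i else j
          } else {
            if (a$concept_id[i] > a$concept_id[j]) i else j
          }
        }
        if (a$match_type[victim] != "COORDINATION") keep[victim] <- FALSE
      }
    }
  }
  a[keep, setdiff(names(a), ".rank")] |>
    arrange(.data$doc_id, .data$start, .data$end, .data$concept_id)
}
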