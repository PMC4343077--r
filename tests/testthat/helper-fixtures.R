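# Shared fixtures (built once per test run) and independent brute-force
# oracles used by the property tests.

fx <- local({
  store <- fixture_concept_store()
  config <- norm_config()
  lexicon <- build_lexicon(store, config)
  list(
    store = store,
    config = config,
    lexicon = lexicon,
    index = build_index(lexicon, store, config),
    lexicon_broad = build_lexicon(store, config,
                                  synonym_scopes = c("EXACT", "BROAD")),
    cmap = assign_categories(store)
  )
})
fx$index_broad <- build_index(fx$lexicon_broad, fx$store, fx$config)

# Independent signature of a phrase: lower-case tokens on whitespace,
# strip edge punctuation, normalize each token, drop stop tokens, sort.
oracle_sig <- function(phrase, config = fx$config) {
  raw <- strsplit(trimws(phrase), "\\s+")[[1]]
  raw <- gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", raw)
  raw <- raw[nzchar(raw)]
  norm <- normalize_token(raw, config)
  sort(norm[!norm %in% config$stopwords], method = "radix")
}

# Brute-force resolution of a phrase against the lexicon table (no index):
# concepts any of whose entries has the same content-token multiset.
oracle_resolve <- function(phrase, lexicon = fx$lexicon, config = fx$config) {
  key <- paste(oracle_sig(phrase, config), collapse = " ")
  if (!nzchar(key)) return(character(0))
  sort(unique(lexicon$concept_id[lexicon$signature == key]))
}

# Enumeration oracle for coordination decomposition: given the qualifier
# tokens, conjunct strings and shared-tail tokens of a synthesized phrase,
# resolve every (qualifier + conjunct + tail) combination independently and
# lay out the spans per the gold-standard guideline semantics.
oracle_decompose <- function(qualifier, conjuncts, tail, conj = "and",
                             lexicon = fx$lexicon, config = fx$config) {
  k <- length(conjuncts)
  sep <- c(rep(", ", max(k - 2, 0)), paste0(" ", conj, " "))
  text <- qualifier
  for (i in seq_len(k)) {
    glue <- if (i == 1) {
      if (nzchar(qualifier)) " " else ""
    } else {
      sep[i - 1]
    }
    text <- paste0(text, glue, conjuncts[i])
  }
  if (nzchar(tail)) text <- paste0(text, " ", tail)
  ids <- lapply(conjuncts, function(x) {
    oracle_resolve(paste(c(qualifier, x, tail), collapse = " "),
                   lexicon, config)
  })
  tail_head <- if (nzchar(tail)) {
    tn <- oracle_sig(tail, config)
    normalize_token(utils::tail(strsplit(tail, "\\s+")[[1]], 1), config)
  } else {
    NA_character_
  }
  case_b <- !nzchar(qualifier) && !is.na(tail_head) &&
    tail_head %in% config$quality_nouns
  resolved <- which(lengths(ids) > 0)
  if (length(resolved) < 2) {
    return(tibble::tibble(start = integer(), end = integer(),
                          concept_id = character()))
  }
  rows <- list()
  if (case_b) {
    for (i in resolved) {
      at <- regexpr(conjuncts[i], text, fixed = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = as.integer(at - 1L), end = nchar(text), concept_id = ids[[i]]
      )
    }
  } else {
    for (i in resolved) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = 0L, end = nchar(text), concept_id = ids[[i]]
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), start, end, concept_id)
}

# Brute-force bipartite matcher on annotation instances (exact equality,
# each instance used at most once).
oracle_align <- function(gold, predicted) {
  gkey <- if (nrow(gold)) {
    paste(gold$doc_id, gold$start, gold$end, gold$concept_id)
  } else {
    character(0)
  }
  pkey <- if (nrow(predicted)) {
    unique(paste(predicted$doc_id, predicted$start, predicted$end,
                 predicted$concept_id))
  } else {
    character(0)
  }
  used <- rep(FALSE, length(pkey))
  tp <- 0L
  for (g in gkey) {
    hit <- which(!used & pkey == g)
    if (length(hit)) {
      used[hit[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(TP = tp, FP = length(pkey) - tp, FN = length(gkey) - tp)
}

# Solvability oracle for generated test-suite entries: every expected
# concept must be reachable from the entry text's content tokens.
oracle_entry_solvable <- function(entry_text, expected,
                                  lexicon = fx$lexicon, config = fx$config) {
  text_sig <- oracle_sig(entry_text, config)
  all(vapply(seq_len(nrow(expected)), function(i) {
    span_txt <- substr(entry_text, expected$start[i] + 1, expected$end[i])
    span_sig <- oracle_sig(span_txt, config)
    cid <- expected$concept_id[i]
    sigs <- strsplit(lexicon$signature[lexicon$concept_id == cid], " ",
                     fixed = TRUE)
    any(vapply(sigs, function(s) all(s %in% span_sig), logical(1)))
  }, logical(1)))
}

random_word <- function(n = 1, min_len = 2, max_len = 12) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}
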