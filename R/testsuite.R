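#' Criterion registry for test-suite generation
#'
#' The default registry is data-driven: fourteen label-length bins (HPO
#' labels range from 1 to 14 tokens), token-content families
#' (punctuation, isolated Arabic and Roman numerals, the six stop words
#' IN/OF/TO/BY/FROM/WITH), lexical-variation and inflection families, the
#' canonical-ordering mirror pair, synonyms, synthesized coordinations,
#' and two curated-input-only families (non-English and metaphoric
#' constructs, which no generator can synthesize faithfully).
#'
#' @return Tibble with columns `criterion_id`, `family`, `param`,
#'   `curated`.
#' @export
criterion_registry <- function() {
  bind_rows(
    tibble(criterion_id = sprintf("length_%02d", 1:14),
           family = "LENGTH", param = 1:14, curated = FALSE),
    tibble(
      criterion_id = c("punctuation", "arabic_numeral", "roman_numeral",
                       "stopword", "singular", "plural", "lexical_variation",
                       "canonical_order", "canonical_order_transformed",
                       "synonym", "coordination", "non_english", "metaphoric"),
      family = c("PUNCTUATION", "ARABIC_NUMERAL", "ROMAN_NUMERAL", "STOPWORD",
                 "SINGULAR", "PLURAL", "LEXICAL_VARIATION", "CANONICAL_ORDER",
                 "CANONICAL_ORDER_TRANSFORMED", "SYNONYM", "COORDINATION",
                 "NON_ENGLISH", "METAPHORIC"),
      param = NA_integer_,
      curated = c(rep(FALSE, 11), TRUE, TRUE)
    )
  )
}

# The six stop words the shape criteria test for (upper-cased in the
# criterion definition; matching is case-insensitive).
CRITERION_STOPWORDS <- c("in", "of", "to", "by", "from", "with")

#' Classify a label into criterion families
#'
#' Deterministic membership tests on one surface form: its length bin,
#' presence of non-hyphen punctuation, isolated Arabic or Roman numerals,
#' one of the six criterion stop words, plus eligibility for the
#' transformation families (canonical-order reordering and
#' singular/plural inflection).
#'
#' @param surface A single label or synonym string.
#' @param config A [norm_config()].
#' @return Character vector of criterion ids.
#' @export
#' @examples
#' classify_label("Meningioma")
#' classify_label("Short metacarpal IV")
classify_label <- function(surface, config = default_norm_config()) {
  tok <- tokenize(surface, config)
  words <- tok[!tok$punct, ]
  out <- sprintf("length_%02d", lengths(strsplit(str_trim(surface), "\\s+")))
  if (grepl("[^[:alnum:][:space:]-]", surface)) out <- c(out, "punctuation")
  if (any(words$arabic)) out <- c(out, "arabic_numeral")
  if (any(words$roman)) out <- c(out, "roman_numeral")
  if (any(tolower(words$text) %in% CRITERION_STOPWORDS)) out <- c(out, "stopword")
  if (!is.na(transform_canonical_order(surface, config))) {
    out <- c(out, "canonical_order", "canonical_order_transformed")
  }
  if (!is.na(label_head_inflectable(surface, config))) {
    out <- c(out, "singular", "plural")
  }
  out
}

#' Transform the canonical token order of a label
#'
#' Produces a fluent reordering with an identical token signature, the
#' "canonical order transformed" variant: `"X of (the) Y"` becomes
#' `"Y X"` ("Hypoplasia of the optic nerve" -> "Optic nerve hypoplasia")
#' and a leading or trailing `type`-qualifier is rotated to the other end
#' ("Type A1 brachydactyly" -> "Brachydactyly type A1").  Returns `NA`
#' when no pattern applies; such labels are skipped by the generator.
#'
#' @inheritParams classify_label
#' @param label The label to reorder.
#' @return A single string, or `NA_character_`.
#' @export
transform_canonical_order <- function(label, config = default_norm_config()) {
  tok <- tokenize(label, config)
  w <- tok[!tok$punct, ]
  n <- nrow(w)
  if (n < 2 || length(token_signature(label, config)) < 2) return(NA_character_)
  decap <- function(x) {
    ifelse(grepl("^[A-Z][a-z]", x), paste0(tolower(substr(x, 1, 1)),
                                           substr(x, 2, nchar(x))), x)
  }
  cap <- function(x) {
    x[1] <- paste0(toupper(substr(x[1], 1, 1)), substr(x[1], 2, nchar(x[1])))
    x
  }
  if (n >= 3 && w$norm[1] == "type") {
    rest <- decap(w$text[3:n])
    return(paste(cap(c(rest, "type", decap(w$text[2]))), collapse = " "))
  }
  of <- which(w$norm == "of")
  if (length(of) && of[1] > 1 && of[1] < n) {
    left <- w$text[seq_len(of[1] - 1)]
    right <- w$text[seq(of[1] + 1, n)]
    if (tolower(right[1]) %in% c("the", "a", "an")) right <- right[-1]
    if (length(right)) {
      return(paste(cap(c(decap(right), decap(left))), collapse = " "))
    }
  }
  if (n >= 3 && w$norm[n - 1] == "type") {
    front <- decap(w$text[seq_len(n - 2)])
    return(paste(cap(c("type", decap(w$text[n]), front)), collapse = " "))
  }
  NA_character_
}

# Head noun = final non-stopword word token; NA when it is a numeral or
# there is no such token.
label_head_inflectable <- function(label, config = default_norm_config()) {
  tok <- tokenize(label, config)
  w <- tok[!tok$punct & !tok$stopword, ]
  if (!nrow(w)) return(NA_integer_)
  h <- nrow(w)
  if (w$arabic[h] || w$roman[h]) return(NA_integer_)
  which(!tok$punct & !tok$stopword &
          tok$start == w$start[h])[1]  # index into word-token order unused; flag only
}

#' Inflect the head noun of a label
#'
#' The head noun is the final non-stopword token; it is inflected to the
#' requested number while all other tokens are untouched.  Returns `NA`
#' when the label is already in the target number or the head is not an
#' inflectable noun (e.g. a numeral).
#'
#' @inheritParams transform_canonical_order
#' @param direction `"SINGULAR"` or `"PLURAL"`.
#' @return A single string, or `NA_character_`.
#' @export
#' @examples
#' inflect_label("Hypoplastic nail", "PLURAL")
#' inflect_label("Short fingers", "SINGULAR")
inflect_label <- function(label, direction = c("SINGULAR", "PLURAL"),
                          config = default_norm_config()) {
  direction <- match.arg(direction)
  out <- inflect_to(label, direction, config)
  if (is.na(out) || identical(out, label)) NA_character_ else out
}

# Like inflect_label() but returns the label unchanged when it is already
# in the target number (used for mirror-pair suite construction).
inflect_to <- function(label, direction, config = default_norm_config()) {
  if (is.na(label_head_inflectable(label, config))) return(NA_character_)
  tok <- tokenize(label, config)
  w <- tok[!tok$punct & !tok$stopword, ]
  h <- nrow(w)
  head_tok <- w$text[h]
  sing <- singularize_token(tolower(head_tok), config)
  plur <- pluralize_token(sing, config)
  if (sing == plur) return(NA_character_)
  target <- if (direction == "SINGULAR") sing else plur
  if (grepl("^[A-Z]", head_tok)) {
    target <- paste0(toupper(substr(target, 1, 1)), substr(target, 2, nchar(target)))
  }
  paste0(substr(label, 1, w$start[h]), target,
         substr(label, w$end[h] + 1, nchar(label)))
}

#' Synthesize a coordination test case from two concepts
#'
#' Builds a composite phrase from two concepts whose lexical groundings
#' share a common token prefix (a preceding qualifier such as
#' "synostosis of ...") or a common token suffix (a shared entity head
#' such as "... fingers", or a shared succeeding quality noun such as
#' "... malformations"), with expected annotations following the
#' gold-standard coordination semantics: `QUAL_FIRST` yields one full
#' span carrying both concepts; `QUAL_LAST` yields nested suffix spans.
#' Returns `NULL` when the two concepts share no usable component
#' (precondition violation -> skip) or when a built phrase would not
#' resolve unambiguously to exactly its two source concepts.
#'
#' @param a,b Concept CURIEs.
#' @param mode `"QUAL_FIRST"` or `"QUAL_LAST"`.
#' @param conj `"and"` or `"or"`.
#' @param lexicon Lexicon tibble ([build_lexicon()]).
#' @param config A [norm_config()].
#' @param category Category CURIE recorded on the entry.
#' @return One-row entries tibble (see [generate_testsuite()]) or `NULL`.
#' @export
synthesize_coordination <- function(a, b, mode = c("QUAL_FIRST", "QUAL_LAST"),
                                    conj = c("and", "or"), lexicon,
                                    config = default_norm_config(),
                                    category = NA_character_) {
  mode <- match.arg(mode)
  conj <- match.arg(conj)
  sig_map <- lexicon_sig_map(lexicon)
  surf_a <- lexicon$surface[lexicon$concept_id == a]
  surf_b <- lexicon$surface[lexicon$concept_id == b]
  for (sa in surf_a) {
    for (sb in surf_b) {
      entry <- try_coordination(sa, sb, a, b, mode, conj, sig_map, config,
                                category)
      if (!is.null(entry)) return(entry)
    }
  }
  NULL
}

lexicon_sig_map <- function(lexicon) {
  d <- distinct(lexicon, .data$signature, .data$concept_id)
  split(d$concept_id, d$signature)
}

resolves_to <- function(phrase, id, sig_map, config) {
  hits <- sig_map[[signature_key(phrase, config)]]
  !is.null(hits) && identical(sort(hits), id)
}

try_coordination <- function(sa, sb, a, b, mode, conj, sig_map, config,
                             category) {
  ta <- tokenize(sa, config); ta <- ta[!ta$punct, ]
  tb <- tokenize(sb, config); tb <- tb[!tb$punct, ]
  na_ <- nrow(ta); nb_ <- nrow(tb)
  cp <- 0L
  while (cp < min(na_, nb_) && ta$norm[cp + 1] == tb$norm[cp + 1]) cp <- cp + 1L
  cs <- 0L
  while (cs < min(na_, nb_) - cp && ta$norm[na_ - cs] == tb$norm[nb_ - cs]) cs <- cs + 1L
  m1 <- if (cp + cs < na_) ta$text[seq(cp + 1, na_ - cs)] else character(0)
  m2 <- if (cp + cs < nb_) tb$text[seq(cp + 1, nb_ - cs)] else character(0)
  if (!length(m1) || !length(m2)) return(NULL)
  # conjuncts must be clean content runs, and no part of the phrase may
  # introduce a second coordinator, or the composite is not decomposable
  m1n <- if (cp + cs < na_) ta$norm[seq(cp + 1, na_ - cs)] else character(0)
  m2n <- if (cp + cs < nb_) tb$norm[seq(cp + 1, nb_ - cs)] else character(0)
  if (any(c(m1n, m2n) %in% c(config$stopwords, "and", "or"))) return(NULL)
  if (any(c(ta$norm, tb$norm) %in% c("and", "or"))) return(NULL)
  prefix <- if (cp > 0) ta$text[seq_len(cp)] else character(0)
  suffix <- if (cs > 0) ta$text[seq(na_ - cs + 1, na_)] else character(0)
  content <- function(x) x[!tolower(x) %in% config$stopwords]
  decap <- function(x) ifelse(grepl("^[A-Z][a-z]", x),
                              paste0(tolower(substr(x, 1, 1)),
                                     substr(x, 2, nchar(x))), x)
  suffix_head <- if (length(content(suffix))) {
    normalize_token(content(suffix)[length(content(suffix))], config)
  } else NA_character_
  expect <- function(text, spans) {
    tibble(criterion_id = "coordination", category = category,
           input_text = text, expected = list(spans))
  }

  if (mode == "QUAL_FIRST") {
    if (!length(content(prefix)) && !length(content(suffix))) return(NULL)
    if (!is.na(suffix_head) && suffix_head %in% config$quality_nouns &&
        !length(content(prefix))) {
      return(NULL)  # this pair decomposes as QUAL_LAST, not QUAL_FIRST
    }
    text <- paste(c(prefix, m1, conj, decap(m2), suffix), collapse = " ")
    if (!resolves_to(paste(c(prefix, m1, suffix), collapse = " "), a, sig_map, config) ||
        !resolves_to(paste(c(prefix, m2, suffix), collapse = " "), b, sig_map, config)) {
      return(NULL)
    }
    spans <- tibble(start = 0L, end = nchar(text),
                    concept_id = sort(c(a, b)))
    return(expect(text, spans))
  }

  # QUAL_LAST: no shared prefix, shared suffix must be a quality noun
  if (length(content(prefix)) || is.na(suffix_head) ||
      !suffix_head %in% config$quality_nouns) {
    return(NULL)
  }
  suffix_pl <- suffix
  last <- length(suffix_pl)
  suffix_pl[last] <- pluralize_token(tolower(suffix_pl[last]), config)
  text <- paste(c(m1, conj, decap(m2), tolower(suffix_pl)), collapse = " ")
  if (!resolves_to(paste(c(m1, suffix), collapse = " "), a, sig_map, config) ||
      !resolves_to(paste(c(m2, suffix), collapse = " "), b, sig_map, config)) {
    return(NULL)
  }
  b_start <- nchar(paste(c(m1, conj), collapse = " ")) + 1L
  spans <- tibble(
    start = c(0L, b_start),
    end = nchar(text),
    concept_id = c(a, b)
  )
  expect(text, spans)
}

#' Generate a stratified test suite from an ontology
#'
#' For each criterion in the registry, eligible lexicon entries are
#' sampled (seeded, deterministic) up to the quota and the family's
#' transformation applied: identity for the shape families, head-noun
#' inflection for singular/plural, token reordering for the
#' canonical-order pair, adjective/noun substitution for lexical
#' variation, synonym substitution, and pairwise phrase synthesis for
#' coordination.  Every generated entry is guaranteed solvable: the
#' transformed text's signature must resolve to exactly the expected
#' concept(s) in the lexicon, otherwise the candidate is skipped.  The
#' {singular, plural} and {canonical order, transformed} suites are
#' mirror pairs built from the same sampled concepts.  Curated families
#' (non-English, metaphoric) are only emitted when an input list is
#' supplied via `curated`; otherwise they are skipped with a warning.
#'
#' @param store A [concept_store()].
#' @param registry A [criterion_registry()] tibble.
#' @param seed Integer seed controlling sampling.
#' @param per_criterion_quota Maximum entries per criterion.
#' @param curated Named list (by criterion id) of tibbles with columns
#'   `input_text`, `concept_id` for curated-input-only families.
#' @param root Category root passed to [assign_categories()].
#' @param config A [norm_config()].
#' @return Entries tibble: `criterion_id`, `category`, `input_text`,
#'   `expected` (list-column of tibbles `start`, `end`, `concept_id`),
#'   plus `concept_id` (primary concept) and `seed` metadata attribute.
#' @export
generate_testsuite <- function(store,
                               registry = criterion_registry(),
                               seed = 1L,
                               per_criterion_quota = 70L,
                               curated = list(),
                               root = "HP:0000118",
                               config = default_norm_config()) {
  stopifnot(inherits(store, "concept_store"))
  lexicon <- build_lexicon(store, config)
  sig_map <- lexicon_sig_map(lexicon)
  cmap <- assign_categories(store, root)
  cat_of <- function(id) {
    cats <- cmap$map$category[cmap$map$concept_id == id]
    if (!length(cats)) "uncategorized" else sort(cats)[1]
  }
  labels <- lexicon[lexicon$provenance == "LABEL", ]
  synonyms <- lexicon[lexicon$provenance == "SYNONYM", ]
  seq_unique <- function(lx) {
    counts <- table(lexicon$norm_seq)
    lx[counts[lx$norm_seq] == 1, ]
  }
  sig_unique <- function(lx) {
    lx[vapply(lx$signature, function(s) length(sig_map[[s]]) == 1, logical(1)), ]
  }
  # deterministic seeded sampling; mirror families share a group seed so
  # the paired suites are built from the same sampled concepts
  pick <- function(df, group, quota = per_criterion_quota) {
    if (!nrow(df)) return(df)
    df <- arrange(df, .data$concept_id, .data$surface)
    g <- sum(utf8ToInt(group))
    withr::with_seed((as.integer(seed) * 1009L + g) %% 2147483647L, {
      df[sort(sample.int(nrow(df), min(quota, nrow(df)))), ]
    })
  }
  identity_entries <- function(df, criterion_id) {
    if (!nrow(df)) return(NULL)
    bind_rows(lapply(seq_len(nrow(df)), function(i) {
      tibble(criterion_id = criterion_id,
             category = cat_of(df$concept_id[i]),
             input_text = df$surface[i],
             expected = list(tibble(start = 0L, end = nchar(df$surface[i]),
                                    concept_id = df$concept_id[i])),
             concept_id = df$concept_id[i])
    }))
  }
  transform_entries <- function(df, criterion_id, f) {
    if (!nrow(df)) return(NULL)
    bind_rows(lapply(seq_len(nrow(df)), function(i) {
      new <- f(df$surface[i])
      if (is.na(new)) return(NULL)
      if (!resolves_to(new, df$concept_id[i], sig_map, config)) return(NULL)
      tibble(criterion_id = criterion_id,
             category = cat_of(df$concept_id[i]),
             input_text = new,
             expected = list(tibble(start = 0L, end = nchar(new),
                                    concept_id = df$concept_id[i])),
             concept_id = df$concept_id[i])
    }))
  }

  out <- list()
  for (r in seq_len(nrow(registry))) {
    fam <- registry$family[r]
    cid <- registry$criterion_id[r]
    if (registry$curated[r]) {
      cur <- curated[[cid]]
      if (is.null(cur)) {
        warning("curated criterion '", cid, "' skipped: no input list supplied",
                call. = FALSE)
        next
      }
      out[[cid]] <- bind_rows(lapply(seq_len(nrow(cur)), function(i) {
        tibble(criterion_id = cid,
               category = cat_of(cur$concept_id[i]),
               input_text = cur$input_text[i],
               expected = list(tibble(start = 0L,
                                      end = nchar(cur$input_text[i]),
                                      concept_id = cur$concept_id[i])),
               concept_id = cur$concept_id[i])
      }))
      next
    }
    out[[cid]] <- switch(
      fam,
      LENGTH = identity_entries(
        pick(seq_unique(labels[labels$token_count == registry$param[r], ]), cid),
        cid),
      PUNCTUATION = identity_entries(
        pick(seq_unique(labels[grepl("[^[:alnum:][:space:]-]", labels$surface), ]),
             cid), cid),
      ARABIC_NUMERAL = identity_entries(
        pick(seq_unique(labels[has_token_flag(labels$surface, "arabic", config), ]),
             cid), cid),
      ROMAN_NUMERAL = identity_entries(
        pick(seq_unique(labels[has_token_flag(labels$surface, "roman", config), ]),
             cid), cid),
      STOPWORD = identity_entries(
        pick(seq_unique(labels[has_criterion_stopword(labels$surface), ]), cid),
        cid),
      SYNONYM = identity_entries(pick(seq_unique(synonyms), cid), cid),
      SINGULAR = transform_entries(
        pick(sig_unique(inflectable(labels, config)), "number_pair"),
        cid, function(s) inflect_to(s, "SINGULAR", config)),
      PLURAL = transform_entries(
        pick(sig_unique(inflectable(labels, config)), "number_pair"),
        cid, function(s) inflect_to(s, "PLURAL", config)),
      CANONICAL_ORDER = identity_entries(
        pick(sig_unique(reorderable(labels, config)), "order_pair"), cid),
      CANONICAL_ORDER_TRANSFORMED = transform_entries(
        pick(sig_unique(reorderable(labels, config)), "order_pair"),
        cid, function(s) transform_canonical_order(s, config)),
      LEXICAL_VARIATION = transform_entries(
        pick(sig_unique(labels), cid),
        cid, function(s) lexical_variant(s, config)),
      COORDINATION = coordination_entries(lexicon, store, sig_map, cat_of,
                                          config, function(df) pick(df, cid)),
      NULL
    )
  }
  entries <- bind_rows(out)
  if (is.null(entries) || !nrow(entries)) {
    entries <- tibble(criterion_id = character(), category = character(),
                      input_text = character(), expected = list(),
                      concept_id = character())
  }
  attr(entries, "seed") <- as.integer(seed)
  entries
}

has_token_flag <- function(surfaces, flag, config) {
  vapply(surfaces, function(s) {
    tok <- tokenize(s, config)
    any(tok[[flag]])
  }, logical(1), USE.NAMES = FALSE)
}

has_criterion_stopword <- function(surfaces) {
  vapply(strsplit(tolower(surfaces), "[^a-z0-9]+"), function(t) {
    any(t %in% CRITERION_STOPWORDS)
  }, logical(1), USE.NAMES = FALSE)
}

inflectable <- function(labels, config) {
  ok <- vapply(labels$surface, function(s) {
    sg <- inflect_to(s, "SINGULAR", config)
    pl <- inflect_to(s, "PLURAL", config)
    !is.na(sg) && !is.na(pl) && sg != pl &&
      signature_key(sg, config) == signature_key(s, config) &&
      signature_key(pl, config) == signature_key(s, config)
  }, logical(1), USE.NAMES = FALSE)
  labels[ok, ]
}

reorderable <- function(labels, config) {
  ok <- vapply(labels$surface, function(s) {
    tr <- transform_canonical_order(s, config)
    !is.na(tr) && signature_key(tr, config) == signature_key(s, config)
  }, logical(1), USE.NAMES = FALSE)
  labels[ok, ]
}

# Adjective/noun lexical variant of "N of (the) E" labels, e.g.
# "Hypoplasia of the optic nerve" -> "Hypoplastic optic nerve".
lexical_variant <- function(label, config = default_norm_config()) {
  tok <- tokenize(label, config)
  w <- tok[!tok$punct, ]
  n <- nrow(w)
  of <- which(w$norm == "of")
  if (!length(of) || of[1] < 2 || of[1] >= n) return(NA_character_)
  noun <- w$norm[of[1] - 1]
  if (of[1] != 2) return(NA_character_)  # single-token quality only
  adj_rows <- config$derivational[config$derivational$pos == "adj" &
                                    config$derivational$normal == noun, ]
  if (!nrow(adj_rows)) return(NA_character_)
  adj <- adj_rows$surface[1]
  right <- w$text[seq(of[1] + 1, n)]
  if (tolower(right[1]) %in% c("the", "a", "an")) right <- right[-1]
  if (!length(right)) return(NA_character_)
  adj <- paste0(toupper(substr(adj, 1, 1)), substr(adj, 2, nchar(adj)))
  paste(c(adj, right), collapse = " ")
}

coordination_entries <- function(lexicon, store, sig_map, cat_of, config,
                                 picker) {
  entries <- lexicon |>
    filter(nzchar(.data$signature)) |>
    arrange(.data$concept_id, .data$surface)
  n <- nrow(entries)
  anc <- lapply(setNames(nm = unique(entries$concept_id)),
                function(id) ancestors(store, id))
  unrelated <- function(x, y) {
    !(x %in% anc[[y]]) && !(y %in% anc[[x]])
  }
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (entries$concept_id[i] == entries$concept_id[j]) next
      if (!unrelated(entries$concept_id[i], entries$concept_id[j])) next
      pairs[[length(pairs) + 1L]] <- tibble(
        concept_id = entries$concept_id[i],  # sampling key
        surface = entries$surface[i],
        b_id = entries$concept_id[j], b_surface = entries$surface[j]
      )
    }
  }
  if (!length(pairs)) return(NULL)
  pairs <- picker(bind_rows(pairs))
  conjs <- c("and", "or")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    conj <- conjs[(i %% 2) + 1L]
    for (mode in c("QUAL_FIRST", "QUAL_LAST")) {
      e <- try_coordination(pairs$surface[i], pairs$b_surface[i],
                            pairs$concept_id[i], pairs$b_id[i],
                            mode, conj, sig_map, config,
                            cat_of(pairs$concept_id[i]))
      if (!is.null(e)) {
        e$concept_id <- pairs$concept_id[i]
        rows[[length(rows) + 1L]] <- e
        break
      }
    }
  }
  if (!length(rows)) return(NULL)
  bind_rows(rows)
}

#' Write / read a test suite as TSV
#'
#' Flat interchange format, one entry per line:
#' `criterion_id TAB category TAB input_text TAB expected`, where
#' `expected` is a semicolon-separated list of `start:end:CURIE` items.
#'
#' @param entries Entries tibble from [generate_testsuite()].
#' @param path Output / input file path.
#' @return `read_testsuite()`: the entries tibble.
#' @export
write_testsuite <- function(entries, path) {
  enc <- vapply(entries$expected, function(e) {
    paste(sprintf("%d:%d:%s", e$start, e$end, e$concept_id), collapse = ";")
  }, character(1))
  lines <- sprintf("%s\t%s\t%s\t%s", entries$criterion_id, entries$category,
                   entries$input_text, enc)
  writeLines(c("criterion_id\tcategory\tinput_text\texpected", lines), path)
  invisible(entries)
}

#' @rdname write_testsuite
#' @export
read_testsuite <- function(path) {
  lines <- readLines(path, warn = FALSE)[-1]
  lines <- lines[nzchar(lines)]
  parts <- str_split(lines, "\t")
  stopifnot(all(lengths(parts) == 4L))
  expected <- lapply(parts, function(p) {
    items <- strsplit(p[[4]], ";", fixed = TRUE)[[1]]
    m <- regmatches(items, regexec("^(\\d+):(\\d+):(.+)$", items))
    stopifnot(all(lengths(m) == 4L))
    tibble(start = as.integer(map_chr(m, 2)),
           end = as.integer(map_chr(m, 3)),
           concept_id = map_chr(m, 4))
  })
  tibble(criterion_id = map_chr(parts, 1),
         category = map_chr(parts, 2),
         input_text = map_chr(parts, 3),
         expected = expected)
}

#' Run an annotator over a test suite
#'
#' Each entry is treated as an individual free-text document; the
#' annotator's output is aligned to the expected annotations with exact
#' boundary matching, which deliberately penalizes systems that also emit
#' concepts nested within the provided label.  Scores are aggregated per
#' criterion and per top-level category.
#'
#' @param entries Entries tibble ([generate_testsuite()] /
#'   [read_testsuite()]).
#' @param annotator A function `(doc_id, text) -> annotation tibble`
#'   with columns `start`, `end`, `concept_id`; see
#'   [recognizer_annotator()].
#' @return A `cr_suite_eval` object with overall, per-criterion and
#'   per-category counts and scores.
#' @export
run_testsuite <- function(entries, annotator) {
  stopifnot(is.function(annotator), nrow(entries) > 0)
  per_entry <- bind_rows(lapply(seq_len(nrow(entries)), function(i) {
    doc_id <- sprintf("tc_%05d", i)
    gold <- mutate(entries$expected[[i]], doc_id = doc_id)
    pred <- annotator(doc_id, entries$input_text[i])
    pred <- as_tibble(pred)
    if (!nrow(pred)) {
      pred <- tibble(doc_id = character(), start = integer(),
                     end = integer(), concept_id = character())
    } else if (!"doc_id" %in% names(pred)) {
      pred$doc_id <- doc_id
    }
    cbind(tibble(criterion_id = entries$criterion_id[i],
                 category = entries$category[i]),
          align_annotations(gold, pred))
  }))
  agg <- function(key) {
    per_entry |>
      group_by(.data[[key]]) |>
      summarise(TP = sum(.data$TP), FP = sum(.data$FP), FN = sum(.data$FN),
                n_entries = n(), .groups = "drop") |>
      (\(d) cbind(d, prf(d)))() |>
      as_tibble()
  }
  counts <- summarise(per_entry, TP = sum(.data$TP), FP = sum(.data$FP),
                      FN = sum(.data$FN))
  structure(
    list(overall = cbind(counts, prf(counts)),
         by_criterion = agg("criterion_id"),
         by_category = agg("category"),
         n_entries = nrow(entries)),
    class = "cr_suite_eval"
  )
}

#' Wrap a recognizer index as a test-suite annotator
#'
#' @param index A [build_index()] object.
#' @param options A [recognizer_options()].
#' @return A function `(doc_id, text) -> annotation tibble`.
#' @export
recognizer_annotator <- function(index, options = recognizer_options()) {
  force(index); force(options)
  function(doc_id, text) annotate_text(text, index, doc_id = doc_id,
                                       options = options)
}

#' @export
print.cr_suite_eval <- function(x, ...) {
  o <- x$overall
  cat("<cr_suite_eval> ", x$n_entries, " entries\n", sep = "")
  cat(sprintf("  TP %d  FP %d  FN %d   P %.2f  R %.2f  F %.2f\n",
              o$TP, o$FP, o$FN, round_half_up(o$precision),
              round_half_up(o$recall), round_half_up(o$f_score)))
  invisible(x)
}

#' Tidiers and plot for test-suite reports
#'
#' @param x,object A `cr_suite_eval`.
#' @param by `"criterion"` or `"category"`.
#' @param ... Unused.
#' @export
tidy.cr_suite_eval <- function(x, by = c("criterion", "category"), ...) {
  by <- match.arg(by)
  if (by == "criterion") x$by_criterion else x$by_category
}

#' @rdname tidy.cr_suite_eval
#' @export
glance.cr_suite_eval <- function(x, ...) {
  as_tibble(cbind(x$overall, tibble(n_entries = x$n_entries)))
}

#' @rdname tidy.cr_suite_eval
#' @export
autoplot.cr_suite_eval <- function(object, by = c("criterion", "category"),
                                   ...) {
  by <- match.arg(by)
  d <- tidy(object, by = by)
  key <- names(d)[1]
  ggplot(d, aes(x = stats::reorder(.data[[key]], .data$f_score),
                y = .data$f_score)) +
    geom_col(fill = "darkorange") +
    coord_flip() +
    labs(x = NULL, y = "F-score (exact boundary)",
         title = paste("Test-suite F-score by", by)) +
    theme_minimal()
}
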