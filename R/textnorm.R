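#' Tokenize text with character offsets
#'
#' Splits on whitespace, then peels leading and trailing punctuation
#' characters off each chunk into their own single-character punctuation
#' tokens.  Hyphenated words (`bell-shaped`, `L4-S1`) are kept whole.
#' Offsets are 0-based, half-open character positions into `text`, so
#' `substr(text, start + 1, end)` reconstructs every token exactly.
#'
#' @param text A single string.
#' @param config A [norm_config()].
#' @return A tibble with one row per token: `text`, `start`, `end`, `norm`
#'   (normalized form, see [normalize_token()]; punctuation tokens keep
#'   their surface), and logical flags `punct`, `stopword`, `arabic`,
#'   `roman`.
#' @export
#' @examples
#' tokenize("segmentation defects in L4-S1")
tokenize <- function(text, config = default_norm_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble(
    text = character(), start = integer(), end = integer(),
    norm = character(), punct = logical(), stopword = logical(),
    arabic = logical(), roman = logical()
  )
  if (is.na(text) || !nzchar(text)) {
    return(empty)
  }
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) {
    return(empty)
  }
  starts <- integer(0)
  ends <- integer(0)   # 1-based inclusive while building
  puncts <- logical(0)
  push <- function(s, e, p) {
    starts[[length(starts) + 1L]] <<- s
    ends[[length(ends) + 1L]] <<- e
    puncts[[length(puncts) + 1L]] <<- p
  }
  lens <- attr(m, "match.length")
  for (k in seq_along(m)) {
    s <- m[k]
    e <- s + lens[k] - 1L
    while (s <= e && is_punct_char(substr(text, s, s))) {
      push(s, s, TRUE)
      s <- s + 1L
    }
    trail <- integer(0)
    while (e >= s && is_punct_char(substr(text, e, e))) {
      trail <- c(e, trail)
      e <- e - 1L
    }
    if (s <= e) push(s, e, FALSE)
    for (pos in trail) push(pos, pos, TRUE)
  }
  tok_text <- substring(text, starts, ends)
  norm <- tok_text
  norm[!puncts] <- normalize_token(tok_text[!puncts], config)
  tibble(
    text = tok_text,
    start = starts - 1L,
    end = ends,
    norm = norm,
    punct = puncts,
    stopword = !puncts & norm %in% config$stopwords,
    arabic = !puncts & grepl("^[0-9]+$", tok_text),
    roman = !puncts & tok_text %in% config$roman
  )
}

is_punct_char <- function(ch) grepl("^[^[:alnum:]]$", ch)

#' Normalize a word token
#'
#' Lower-cases, singularizes (irregular table, then `-ies`/`-es`/`-s`
#' rules) and maps derivational variants through the configured exception
#' table, in that order.  The pipeline is idempotent:
#' `normalize_token(normalize_token(x)) == normalize_token(x)`.
#'
#' @param token Character vector of word tokens.
#' @inheritParams tokenize
#' @return Character vector of normal forms.
#' @export
#' @examples
#' normalize_token(c("Nails", "hypoplastic", "metacarpals"))
normalize_token <- function(token, config = default_norm_config()) {
  t <- singularize_token(tolower(token), config)
  hit <- unname(config$derivational_map[t])
  ifelse(is.na(hit), t, hit)
}

#' Singular and plural forms of a token
#'
#' Rule-based number inflection used both by normalization and by the
#' singular/plural test-suite families.  `singularize_token()` consults the
#' irregular table first, then strips regular plural endings; tokens ending
#' in `-ss`, `-us` or `-is` (synostosis, pectus, ...) are left alone.
#' `pluralize_token()` is its rough inverse on regular nouns.
#'
#' @inheritParams normalize_token
#' @return Character vector.
#' @export
singularize_token <- function(token, config = default_norm_config()) {
  vapply(token, function(t) {
    irr <- unname(config$irregular_map[t])
    if (!is.na(irr)) return(irr)
    n <- nchar(t)
    if (n > 4 && grepl("ies$", t)) return(sub("ies$", "y", t))
    if (n > 3 && grepl("(ses|xes|zes|ches|shes)$", t)) return(sub("es$", "", t))
    if (n > 3 && grepl("s$", t) && !grepl("(ss|us|is)$", t)) return(sub("s$", "", t))
    t
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname singularize_token
#' @export
pluralize_token <- function(token, config = default_norm_config()) {
  vapply(token, function(t) {
    irr <- unname(config$irregular_rev[t])
    if (!is.na(irr)) return(irr)
    if (grepl("[^aeiou]y$", t)) return(sub("y$", "ies", t))
    if (grepl("(s|x|z|ch|sh)$", t)) return(paste0(t, "es"))
    paste0(t, "s")
  }, character(1), USE.NAMES = FALSE)
}

#' Order-free token signature of a phrase
#'
#' The signature is the multiset of normalized content tokens (punctuation
#' and stop tokens removed), canonically serialized as the sorted token
#' sequence.  Two surface forms with equal signatures are treated as
#' order-invariant lexical groundings of the same phrase, e.g.
#' `"Hypoplasia of the optic nerve"` and `"Optic nerve hypoplasia"`.
#'
#' @param x A single string, or a token tibble from [tokenize()].
#' @inheritParams tokenize
#' @return `token_signature()`: sorted character vector (possibly empty);
#'   `signature_key()`: its single-string serialization.
#' @export
#' @examples
#' signature_key("Optic nerve hypoplasia") ==
#'   signature_key("Hypoplasia of the optic nerve")
token_signature <- function(x, config = default_norm_config()) {
  tok <- if (is.data.frame(x)) x else tokenize(x, config)
  sort(tok$norm[!tok$punct & !tok$stopword], method = "radix")
}

#' @rdname token_signature
#' @export
signature_key <- function(x, config = default_norm_config()) {
  paste(token_signature(x, config), collapse = " ")
}

# Normalized token sequence (order preserved, stop tokens kept, punctuation
# dropped); the key used for exact-surface index lookups.
norm_seq_key <- function(x, config = default_norm_config()) {
  tok <- if (is.data.frame(x)) x else tokenize(x, config)
  paste(tok$norm[!tok$punct], collapse = " ")
}
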