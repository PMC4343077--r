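#' Build the matchable lexicon from a concept store
#'
#' One row per matchable surface form: the preferred label of every
#' non-obsolete concept plus its synonyms in the requested scopes.  Each
#' entry carries its normalized token sequence (`norm_seq`), its
#' order-free token `signature` (see [token_signature()]) and its
#' whitespace token count.  Obsolete concepts contribute no entries.
#'
#' @param store A [concept_store()].
#' @param config A [norm_config()].
#' @param synonym_scopes Synonym scopes admitted into the lexicon.  The
#'   default admits only EXACT synonyms alongside labels; broader scopes
#'   can be opted in (`c("EXACT", "BROAD", ...)`).
#' @param include_labels Include preferred labels (default `TRUE`).
#' @return A tibble with columns `concept_id`, `surface`, `provenance`
#'   (`LABEL` or `SYNONYM`), `scope`, `norm_seq`, `signature`,
#'   `token_count`.
#' @export
#' @examples
#' lex <- build_lexicon(fixture_concept_store())
#' dplyr::filter(lex, concept_id == "HP:0000609")
build_lexicon <- function(store,
                          config = default_norm_config(),
                          synonym_scopes = "EXACT",
                          include_labels = TRUE) {
  stopifnot(inherits(store, "concept_store"))
  live <- store$concepts[!store$concepts$obsolete, ]
  pieces <- list()
  if (include_labels) {
    pieces$labels <- tibble(
      concept_id = live$id,
      surface = live$label,
      provenance = "LABEL",
      scope = NA_character_
    )
  }
  syn <- store$synonyms[store$synonyms$id %in% live$id &
                          store$synonyms$scope %in% synonym_scopes, ]
  if (nrow(syn)) {
    pieces$synonyms <- tibble(
      concept_id = syn$id,
      surface = syn$synonym,
      provenance = "SYNONYM",
      scope = syn$scope
    )
  }
  lex <- bind_rows(pieces)
  if (is.null(lex) || !nrow(lex)) stop("empty lexicon")
  lex$norm_seq <- vapply(lex$surface, norm_seq_key, character(1),
                         config = config, USE.NAMES = FALSE)
  lex$signature <- vapply(lex$surface, signature_key, character(1),
                          config = config, USE.NAMES = FALSE)
  lex$token_count <- lengths(strsplit(str_trim(lex$surface), "\\s+"))
  arrange(lex, .data$concept_id, .data$provenance, .data$surface)
}

#' Build the retrieval index over a lexicon
#'
#' Hash maps from (a) exact normalized token sequences and (b) canonical
#' signatures to the lexicon entries carrying them.  Several concepts may
#' share a signature; the index is a multimap and preserves that
#' ambiguity for the recognizer to resolve (or refuse).
#'
#' @param lexicon A lexicon tibble from [build_lexicon()].
#' @param store The [concept_store()] the lexicon came from (used for
#'   hierarchy-aware overlap resolution).
#' @param config The [norm_config()] that built the lexicon.
#' @return An object of class `cr_index`.
#' @export
build_index <- function(lexicon, store, config = default_norm_config()) {
  stopifnot(is.data.frame(lexicon), nrow(lexicon) > 0, inherits(store, "concept_store"))
  exact <- new.env(parent = emptyenv(), hash = TRUE)
  sig <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(lexicon))) {
    ks <- lexicon$norm_seq[i]
    if (nzchar(ks)) assign(ks, c(get0(ks, envir = exact), i), envir = exact)
    kg <- lexicon$signature[i]
    if (nzchar(kg)) assign(kg, c(get0(kg, envir = sig), i), envir = sig)
  }
  structure(
    list(lexicon = lexicon, exact = exact, sig = sig,
         store = store, config = config),
    class = "cr_index"
  )
}

#' @export
print.cr_index <- function(x, ...) {
  cat("<cr_index> ", nrow(x$lexicon), " lexicon entries over ",
      length(unique(x$lexicon$concept_id)), " concepts\n", sep = "")
  invisible(x)
}

# Concept ids reachable from an exact normalized-sequence key / a signature
# key; sorted for determinism.
index_exact_ids <- function(index, key) {
  rows <- get0(key, envir = index$exact)
  if (is.null(rows)) character(0) else
    sort(unique(index$lexicon$concept_id[rows]), method = "radix")
}

index_sig_ids <- function(index, key) {
  if (!nzchar(key)) return(character(0))
  rows <- get0(key, envir = index$sig)
  if (is.null(rows)) character(0) else
    sort(unique(index$lexicon$concept_id[rows]), method = "radix")
}

# Resolve an arbitrary token-norm vector order-invariantly.
resolve_norms <- function(index, norms, stop = index$config$stopwords) {
  content <- norms[!norms %in% stop]
  if (!length(content)) return(character(0))
  index_sig_ids(index, paste(sort(content, method = "radix"), collapse = " "))
}
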