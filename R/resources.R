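#' Normalization configuration
#'
#' Bundles the resources shared by tokenization, lexicon indexing and
#' matching: the stop-token list, the derivational-variant table
#' (adjective/noun variants mapped to one normal form, e.g.
#' `hypoplastic -> hypoplasia`), the irregular-plural table and the list of
#' quality head nouns used to decide how a coordination decomposes.  All
#' four default to plain-text resource files shipped under
#' `inst/extdata/`, so every table is user-replaceable.
#'
#' @param stopwords Character vector of stop tokens (lower case).
#' @param derivational Data frame with columns `surface`, `normal`, `pos`.
#' @param irregular_plurals Data frame with columns `plural`, `singular`.
#' @param quality_nouns Character vector of normalized quality head nouns.
#' @return An object of class `norm_config`.
#' @export
#' @examples
#' cfg <- norm_config()
#' normalize_token("Nails", cfg)
norm_config <- function(stopwords = NULL,
                        derivational = NULL,
                        irregular_plurals = NULL,
                        quality_nouns = NULL) {
  stopwords <- stopwords %||% read_word_list(res_path("stopwords.txt"))
  derivational <- derivational %||% read_tsv_resource(res_path("derivational.tsv"))
  irregular_plurals <- irregular_plurals %||%
    read_tsv_resource(res_path("irregular_plurals.tsv"))
  quality_nouns <- quality_nouns %||% read_word_list(res_path("quality_nouns.txt"))
  stopifnot(
    all(c("surface", "normal") %in% names(derivational)),
    all(c("plural", "singular") %in% names(irregular_plurals))
  )
  structure(
    list(
      stopwords = tolower(stopwords),
      derivational = derivational,
      derivational_map = setNames(derivational$normal, derivational$surface),
      irregular_map = setNames(irregular_plurals$singular, irregular_plurals$plural),
      irregular_rev = setNames(irregular_plurals$plural, irregular_plurals$singular),
      quality_nouns = tolower(quality_nouns),
      roman = as.character(utils::as.roman(1:20))
    ),
    class = "norm_config"
  )
}

#' @export
print.norm_config <- function(x, ...) {
  cat("<norm_config>\n")
  cat("  stop tokens:        ", length(x$stopwords), "\n")
  cat("  derivational pairs: ", nrow(x$derivational), "\n")
  cat("  irregular plurals:  ", nrow(x$irregular_plurals %||% x$derivational[0, ]), "\n")
  cat("  quality nouns:      ", length(x$quality_nouns), "\n")
  invisible(x)
}

res_path <- function(...) {
  system.file("extdata", ..., package = "phenorec", mustWork = TRUE)
}

read_word_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- str_trim(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

read_tsv_resource <- function(path) {
  read.delim(path, sep = "\t", quote = "", comment.char = "#",
             stringsAsFactors = FALSE)
}

# Cached default so repeated tokenize()/annotate calls do not re-read files.
default_norm_config <- function() {
  if (is.null(.phenorec$norm_config)) {
    .phenorec$norm_config <- norm_config()
  }
  .phenorec$norm_config
}
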