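#' Concept store
#'
#' A validated, deterministic container for an ontology subset: one tibble
#' of concepts (`id`, `label`, `obsolete`), one of synonyms (`id`,
#' `synonym`, `scope`) and one of `is_a` edges (`id`, `parent`).  Only
#' `is_a` edges are represented; HPO is is_a-structured for the purposes of
#' lexicon building and category assignment.
#'
#' @param concepts Tibble with columns `id`, `label`, `obsolete`.
#' @param synonyms Tibble with columns `id`, `synonym`, `scope`
#'   (one of EXACT, BROAD, NARROW, RELATED).
#' @param parents Tibble with columns `id`, `parent`.
#' @param id_pattern Regular expression every concept id must match; the
#'   default accepts the HPO CURIE shape `HP:` + 7 digits, with the prefix
#'   left configurable for other ontologies.
#' @return An object of class `concept_store`.
#' @export
concept_store <- function(concepts,
                          synonyms = tibble(id = character(), synonym = character(),
                                            scope = character()),
                          parents = tibble(id = character(), parent = character()),
                          id_pattern = "^[A-Za-z]+:\\d{7}$") {
  concepts <- as_tibble(concepts)
  synonyms <- as_tibble(synonyms)
  parents <- as_tibble(parents)
  if (anyDuplicated(concepts$id)) {
    stop("duplicate concept id(s): ",
         paste(unique(concepts$id[duplicated(concepts$id)]), collapse = ", "))
  }
  bad <- concepts$id[!grepl(id_pattern, concepts$id)]
  if (length(bad)) {
    stop("concept id(s) not matching '", id_pattern, "': ",
         paste(bad, collapse = ", "))
  }
  if (any(!nzchar(concepts$label) | is.na(concepts$label))) {
    stop("every concept needs a non-empty label")
  }
  self <- parents$id == parents$parent
  if (any(self)) {
    stop("concept(s) listing themselves as parent: ",
         paste(parents$id[self], collapse = ", "))
  }
  bad_scope <- setdiff(unique(synonyms$scope), c("EXACT", "BROAD", "NARROW", "RELATED"))
  if (length(bad_scope)) {
    stop("unknown synonym scope(s): ", paste(bad_scope, collapse = ", "))
  }
  structure(
    list(
      concepts = arrange(concepts, .data$id),
      synonyms = arrange(synonyms, .data$id, .data$synonym),
      parents = arrange(parents, .data$id, .data$parent),
      id_pattern = id_pattern
    ),
    class = "concept_store"
  )
}

#' @export
print.concept_store <- function(x, ...) {
  cat("<concept_store> ", nrow(x$concepts), " concepts (",
      sum(x$concepts$obsolete), " obsolete), ",
      nrow(x$synonyms), " synonyms, ",
      nrow(x$parents), " is_a edges\n", sep = "")
  invisible(x)
}

#' Read an OBO 1.2 flat file (subset)
#'
#' Parses `[Term]` stanzas with the keys `id`, `name`, `is_a`, `synonym`
#' and `is_obsolete` into a [concept_store()].  Parsing is deterministic;
#' a malformed line inside a term stanza is an error naming its line
#' number, as is a duplicate id.
#'
#' @param path Path to an OBO file; alternatively pass the file content as
#'   a character vector of `lines`.
#' @param lines Character vector of OBO lines (overrides `path`).
#' @inheritParams concept_store
#' @return A `concept_store`.
#' @export
read_obo <- function(path = NULL, lines = NULL, id_pattern = "^[A-Za-z]+:\\d{7}$") {
  if (is.null(lines)) {
    if (is.null(path) || !file.exists(path)) {
      stop("OBO file not found: ", path %||% "<NULL>")
    }
    lines <- readLines(path, warn = FALSE)
  }
  terms <- list()
  cur <- NULL
  cur_line <- NA_integer_
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur)) {
      if (is.null(cur$id) || is.null(cur$name)) {
        stop("malformed [Term] stanza starting at line ", cur_line,
             ": missing id or name")
      }
      terms[[length(terms) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, "[")) {
      flush()
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, name = NULL, is_a = character(0),
                    synonyms = list(), obsolete = FALSE)
        cur_line <- i
      }
      next
    }
    if (!in_term) next  # header / other stanzas ignored
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) {
      stop("malformed OBO line ", i, ": ", line)
    }
    key <- m[2]
    value <- m[3]
    if (key == "synonym") {
      sm <- regmatches(
        value,
        regexec("^\"(.*)\"\\s*(EXACT|BROAD|NARROW|RELATED)?\\s*(\\[[^]]*\\])?\\s*$", value)
      )[[1]]
      if (length(sm) < 2L || !nzchar(sm[2])) {
        stop("malformed synonym at line ", i, ": ", line)
      }
      scope <- if (length(sm) >= 3L && nzchar(sm[3])) sm[3] else "RELATED"
      cur$synonyms[[length(cur$synonyms) + 1L]] <- c(surface = sm[2], scope = scope)
    } else {
      value <- sub("\\s+!.*$", "", value)  # trailing OBO comment
      switch(key,
        id = {
          cur$id <- value
        },
        name = {
          cur$name <- value
        },
        is_a = {
          cur$is_a <- c(cur$is_a, strsplit(value, "\\s+")[[1]][1])
        },
        is_obsolete = {
          cur$obsolete <- identical(tolower(value), "true")
        },
        NULL  # other term keys tolerated and ignored
      )
    }
  }
  flush()
  concepts <- tibble(
    id = map_chr(terms, "id"),
    label = map_chr(terms, "name"),
    obsolete = map_lgl(terms, "obsolete")
  )
  synonyms <- bind_rows(lapply(terms, function(t) {
    if (!length(t$synonyms)) return(NULL)
    tibble(
      id = t$id,
      synonym = map_chr(t$synonyms, "surface"),
      scope = map_chr(t$synonyms, "scope")
    )
  }))
  if (is.null(synonyms) || !nrow(synonyms)) {
    synonyms <- tibble(id = character(), synonym = character(), scope = character())
  }
  parents <- bind_rows(lapply(terms, function(t) {
    if (!length(t$is_a)) return(NULL)
    tibble(id = t$id, parent = t$is_a)
  }))
  if (is.null(parents) || !nrow(parents)) {
    parents <- tibble(id = character(), parent = character())
  }
  concept_store(concepts, synonyms, parents, id_pattern = id_pattern)
}

#' Serialize a concept store back to OBO text
#'
#' Writes the canonical OBO form used throughout the package: terms sorted
#' by id; within a term `id`, `name`, `synonym` (sorted), `is_a` (sorted),
#' then `is_obsolete`.  `read_obo()` followed by `write_obo()` is a fixed
#' point on text produced by this serializer.
#'
#' @param store A `concept_store`.
#' @param path Optional output file; when `NULL` the text is returned.
#' @return Invisibly (or visibly when `path` is `NULL`) a single string.
#' @export
write_obo <- function(store, path = NULL) {
  stopifnot(inherits(store, "concept_store"))
  header <- c("format-version: 1.2", "")
  blocks <- lapply(store$concepts$id, function(cid) {
    row <- store$concepts[store$concepts$id == cid, ]
    syn <- store$synonyms[store$synonyms$id == cid, ]
    par <- store$parents[store$parents$id == cid, ]
    lab <- vapply(store$concepts$label[match(par$parent, store$concepts$id)],
                  function(x) if (is.na(x)) "" else x, character(1))
    c("[Term]",
      paste0("id: ", cid),
      paste0("name: ", row$label),
      if (nrow(syn)) paste0("synonym: \"", syn$synonym, "\" ", syn$scope, " []"),
      if (nrow(par)) paste0("is_a: ", par$parent,
                            ifelse(nzchar(lab), paste0(" ! ", lab), "")),
      if (row$obsolete) "is_obsolete: true",
      "")
  })
  text <- paste(c(header, unlist(blocks)), collapse = "\n")
  if (!is.null(path)) {
    cat(text, file = path)
    return(invisible(text))
  }
  text
}

#' Ancestors of a concept
#'
#' Reflexive-free transitive closure over `is_a` edges.  Errors on an
#' unknown id, and on a cycle through `id` (naming the cycle).
#'
#' @param store A `concept_store`.
#' @param id A concept CURIE present in `store`.
#' @return Sorted character vector of ancestor ids (possibly empty).
#' @export
#' @examples
#' store <- fixture_concept_store()
#' ancestors(store, "HP:0000250")
ancestors <- function(store, id) {
  stopifnot(inherits(store, "concept_store"))
  if (!id %in% store$concepts$id) stop("unknown concept id: ", id)
  parent_of <- split(store$parents$parent, store$parents$id)
  seen <- character(0)
  frontier <- parent_of[[id]] %||% character(0)
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(parent_of[new], use.names = FALSE))
  }
  if (id %in% seen) {
    stop("cycle detected through ", id, " (closure: ",
         paste(sort(seen), collapse = " -> "), ")")
  }
  sort(intersect(seen, store$concepts$id), method = "radix")
}

# Depth of each concept: longest is_a path above it.  Used as the
# specificity tie-break when overlapping annotations must be resolved.
concept_depths <- function(store) {
  parent_of <- split(store$parents$parent, store$parents$id)
  memo <- new.env(parent = emptyenv())
  depth <- function(id, active = character(0)) {
    got <- get0(id, envir = memo)
    if (!is.null(got)) return(got)
    if (id %in% active) stop("cycle detected at ", id)
    ps <- intersect(parent_of[[id]] %||% character(0), store$concepts$id)
    d <- if (!length(ps)) 0L else 1L + max(vapply(ps, depth, integer(1),
                                                 active = c(active, id)))
    assign(id, d, envir = memo)
    d
  }
  setNames(vapply(store$concepts$id, depth, integer(1)), store$concepts$id)
}

#' Assign top-level categories
#'
#' Maps every concept to the direct children of `root` (by default
#' HP:0000118, *Phenotypic abnormality*, reproducing the standard
#' 21-top-level-category stratification of HPO) that lie on some is_a path
#' above it.  A concept with multiple ancestry paths may map to more than
#' one category; a concept outside the `root` subtree maps to none.
#'
#' @inheritParams ancestors
#' @param root CURIE of the category root.
#' @return An object of class `category_map`: list with `root`,
#'   `categories` (tibble `id`, `label`) and `map`
#'   (tibble `concept_id`, `category`).
#' @export
#' @examples
#' cm <- assign_categories(fixture_concept_store())
#' categories_of(cm, "HP:0000250")  # two categories via multiple inheritance
assign_categories <- function(store, root = "HP:0000118") {
  stopifnot(inherits(store, "concept_store"))
  if (!root %in% store$concepts$id) stop("unknown category root: ", root)
  cats <- sort(store$parents$id[store$parents$parent == root], method = "radix")
  rows <- lapply(store$concepts$id, function(cid) {
    hit <- intersect(cats, c(ancestors(store, cid), cid))
    if (!length(hit)) return(NULL)
    tibble(concept_id = cid, category = hit)
  })
  map <- bind_rows(rows)
  if (is.null(map) || !nrow(map)) {
    map <- tibble(concept_id = character(), category = character())
  }
  structure(
    list(
      root = root,
      categories = tibble(
        id = cats,
        label = store$concepts$label[match(cats, store$concepts$id)]
      ),
      map = map
    ),
    class = "category_map"
  )
}

#' @export
print.category_map <- function(x, ...) {
  cat("<category_map> root ", x$root, ", ", nrow(x$categories),
      " categories, ", nrow(x$map), " concept-category pairs\n", sep = "")
  invisible(x)
}

#' @rdname assign_categories
#' @param cmap A `category_map`.
#' @param ids Character vector of concept ids.
#' @return `categories_of()`: list (one element per id) of category CURIEs.
#' @export
categories_of <- function(cmap, ids) {
  stopifnot(inherits(cmap, "category_map"))
  lapply(ids, function(cid) cmap$map$category[cmap$map$concept_id == cid])
}
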