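# Self-contained synthetic fixtures: a mini-ontology in the HPO id space
# and a small gold corpus exercising the annotation guidelines
# (canonical-form spans, both coordination cases, negation kept).  They
# exist so the whole toolkit can be built and tested without downloading
# the real HPO; hierarchy placements are simplified and concepts the
# sources mention without an id use the reserved HP:02000xx range.

fixture_terms <- function() {
  t <- function(id, label, parents = character(0), syn = list(), obsolete = FALSE) {
    list(id = id, label = label, parents = parents, syn = syn, obsolete = obsolete)
  }
  s <- function(surface, scope = "EXACT") c(surface = surface, scope = scope)
  list(
    t("HP:0000001", "All"),
    t("HP:0000118", "Phenotypic abnormality", "HP:0000001"),
    # top-level categories (subset of the 21)
    t("HP:0000119", "Abnormality of the genitourinary system", "HP:0000118"),
    t("HP:0000152", "Abnormality of the head and neck", "HP:0000118"),
    t("HP:0000598", "Abnormality of the ear", "HP:0000118"),
    t("HP:0000707", "Abnormality of the nervous system", "HP:0000118"),
    t("HP:0000924", "Abnormality of the skeletal system", "HP:0000118"),
    t("HP:0001507", "Growth abnormality", "HP:0000118"),
    t("HP:0001574", "Abnormality of the integument", "HP:0000118"),
    t("HP:0002664", "Neoplasm", "HP:0000118", list(s("Tumour"))),
    # skeletal
    t("HP:0001167", "Abnormality of finger", "HP:0000924"),
    t("HP:0009381", "Short fingers", "HP:0001167"),
    t("HP:0001500", "Broad fingers", "HP:0001167"),
    t("HP:0001156", "Brachydactyly", "HP:0001167"),
    t("HP:0009371", "Type A1 brachydactyly", "HP:0001156"),
    t("HP:0200006", "Brachydactyly type 3", "HP:0001156"),
    t("HP:0200003", "Short metacarpal IV", "HP:0000924"),
    t("HP:0001591", "Bell-shaped thorax", "HP:0000924"),
    t("HP:0008368", "Synostosis involving tarsal bones", "HP:0000924",
      list(s("Synostosis of tarsal bones"), s("Tarsal bone synostosis"))),
    t("HP:0009702", "Synostosis involving the carpal bones", "HP:0000924",
      list(s("Synostosis of carpal bones"), s("Carpal bone synostosis"))),
    t("HP:0002683", "Abnormality of the calvaria", "HP:0000924"),
    # head & neck / ear
    t("HP:0004330", "Increased skull ossification", "HP:0000152"),
    t("HP:0000250", "Dense calvaria", c("HP:0002683", "HP:0004330")),
    t("HP:0009794", "Branchial anomaly", "HP:0000152",
      list(s("Branchial arch malformation"))),
    # genitourinary
    t("HP:0000077", "Abnormality of the kidney", "HP:0000119"),
    t("HP:0000792", "Abnormal renal morphology", "HP:0000077",
      list(s("Renal malformation"), s("Kidney anomaly", "BROAD"))),
    # nervous system
    t("HP:0000609", "Hypoplasia of the optic nerve", "HP:0000707",
      list(s("Optic nerve hypoplasia"))),
    t("HP:0000733", "Stereotypical motor behaviours", "HP:0000707"),
    t("HP:0007087", "Involuntary jerking movements", "HP:0000707"),
    # integument
    t("HP:0200001", "Aplasia of the nail", "HP:0001574", list(s("Aplastic nails"))),
    t("HP:0200002", "Hypoplasia of the nail", "HP:0001574",
      list(s("Hypoplastic nails"), s("Nail hypoplasia"))),
    t("HP:0200005", "Aplasia/Hypoplasia of the nails", "HP:0001574"),
    # growth / neoplasm
    t("HP:0004322", "Short stature", "HP:0001507", list(s("Decreased body height"))),
    t("HP:0002858", "Meningioma", "HP:0002664"),
    # obsolete concepts must contribute nothing to the lexicon
    t("HP:0200099", "Aplasia of the philtrum (obsolete fixture term)",
      obsolete = TRUE)
  )
}

#' Synthetic fixture ontology
#'
#' `build_fixture_ontology()` returns deterministic OBO 1.2 text for a
#' small synthetic mini-ontology in the HPO id space: a category skeleton
#' under HP:0000118, multi-parent concepts (HP:0000250 *Dense calvaria*
#' sits under both a skeletal and a head-and-neck path), synonyms for the
#' worked coordination and reordering examples, and one obsolete term.
#' `fixture_concept_store()` is the parsed equivalent.
#'
#' @return OBO text (single string) / a [concept_store()].
#' @export
#' @examples
#' store <- fixture_concept_store()
#' store
build_fixture_ontology <- function() {
  terms <- fixture_terms()
  concepts <- tibble(
    id = map_chr(terms, "id"),
    label = map_chr(terms, "label"),
    obsolete = map_lgl(terms, "obsolete")
  )
  synonyms <- bind_rows(lapply(terms, function(t) {
    if (!length(t$syn)) return(NULL)
    tibble(id = t$id,
           synonym = map_chr(t$syn, "surface"),
           scope = map_chr(t$syn, "scope"))
  }))
  parents <- bind_rows(lapply(terms, function(t) {
    if (!length(t$parents)) return(NULL)
    tibble(id = t$id, parent = t$parents)
  }))
  write_obo(concept_store(concepts, synonyms, parents))
}

#' @rdname build_fixture_ontology
#' @export
fixture_concept_store <- function() {
  if (is.null(.phenorec$fixture_store)) {
    .phenorec$fixture_store <- read_obo(lines = strsplit(build_fixture_ontology(), "\n")[[1]])
  }
  .phenorec$fixture_store
}

#' Synthetic fixture gold corpus
#'
#' Six one-sentence documents with gold annotations exercising the corpus
#' annotation guidelines: canonical-form spans, qualifier-preceding
#' coordination (one full span, two concepts), qualifier-succeeding
#' coordination (three nested suffix spans), a negated span that is still
#' annotated, a canonical-order-transformed mention and a
#' qualifier-coordination over a shared entity.  Offsets are computed, not
#' hand-typed, so the corpus always validates.
#'
#' @return A `gold_corpus` (see [read_gold()]): list of tibbles
#'   `documents` (`doc_id`, `text`) and `annotations`
#'   (`doc_id`, `start`, `end`, `matched_text`, `concept_id`).
#' @export
fixture_gold_corpus <- function() {
  span <- function(doc_id, text, phrase, ids) {
    at <- regexpr(phrase, text, fixed = TRUE)
    stopifnot(at > 0)
    tibble(
      doc_id = doc_id,
      start = as.integer(at - 1L),
      end = as.integer(at - 1L + nchar(phrase)),
      matched_text = phrase,
      concept_id = ids
    )
  }
  docs <- tibble(
    doc_id = paste0("gs_0", 1:6),
    text = c(
      "Both patients had hypoplastic nails.",
      "Radiographs revealed synostosis of some carpal and tarsal bones.",
      "The syndrome is characterised by branchial arch, otic and renal malformations.",
      "No kidney anomalies were found in the affected siblings.",
      "Brachydactyly type A1 was diagnosed in the proband.",
      "She had short and broad fingers."
    )
  )
  txt <- setNames(docs$text, docs$doc_id)
  ann <- bind_rows(
    span("gs_01", txt[["gs_01"]], "hypoplastic nails", "HP:0200002"),
    span("gs_02", txt[["gs_02"]], "synostosis of some carpal and tarsal bones",
         c("HP:0008368", "HP:0009702")),
    span("gs_03", txt[["gs_03"]], "branchial arch, otic and renal malformations",
         "HP:0009794"),
    span("gs_03", txt[["gs_03"]], "otic and renal malformations", "HP:0000598"),
    span("gs_03", txt[["gs_03"]], "renal malformations", "HP:0000792"),
    span("gs_04", txt[["gs_04"]], "kidney anomalies", "HP:0000077"),
    span("gs_05", txt[["gs_05"]], "Brachydactyly type A1", "HP:0009371"),
    span("gs_06", txt[["gs_06"]], "short and broad fingers",
         c("HP:0001500", "HP:0009381"))
  )
  new_gold_corpus(docs, arrange(ann, .data$doc_id, .data$start, .data$end,
                                .data$concept_id))
}
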