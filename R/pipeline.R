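# sentence text normalized for pairing selected sentences with parse blocks
sentence_fingerprint <- function(x) {
  tolower(stringr::str_squish(gsub("[^[:alnum:] ]", "", x)))
}

graph_fingerprint <- function(graph) {
  sentence_fingerprint(paste(graph$tokens$surface, collapse = " "))
}

#' Run the extraction stage over a corpus
#'
#' Reads MEDLINE-style abstracts, selects effect-word sentences, pairs each
#' with its parse graph (matched by normalized sentence text), applies the
#' rulebook and normalizes the raw extractions into SEPDB relations.
#' Sentences without a parse graph, without an applicable rule, or whose
#' extraction is rejected are skipped.
#'
#' @param xml_path MEDLINE-style XML file.
#' @param parse_path parse-graph interchange file covering (at least) the
#'   effect sentences.
#' @param rulebook list of [extraction_rule()] objects, or a rulebook file
#'   path.
#' @param lexicon a [semantic_lexicon()] tibble, or a TSV path.
#' @param effect_lexicon effect lexicon tibble, or a TSV path.
#' @param config a [upk_config()] list.
#' @param quiet suppress per-sentence notes.
#' @return relations tibble (deduplicated) with provenance columns.
#' @export
run_extraction <- function(xml_path, parse_path, rulebook,
                           lexicon, effect_lexicon = default_effect_lexicon(),
                           config = upk_config(), quiet = TRUE) {
  if (is.character(rulebook)) rulebook <- read_rulebook(rulebook)
  if (is.character(lexicon)) lexicon <- read_semantic_lexicon(lexicon)
  if (is.character(effect_lexicon)) effect_lexicon <- read_effect_lexicon(effect_lexicon)

  abstracts <- read_medline_xml(xml_path)
  matches <- select_sentences(abstracts, effect_lexicon)
  graphs <- read_parse_file(parse_path, lexicon = effect_lexicon)
  graphs <- purrr::map(graphs, function(g) if (inherits(g, "tagged_sentence")) g$graph else g)
  gmap <- stats::setNames(graphs, vapply(graphs, graph_fingerprint, character(1)))

  rule_stems <- unique(vapply(rulebook, function(r) r$effect_stem, character(1)))
  rels <- list()
  for (k in seq_len(nrow(matches))) {
    m <- matches[k, ]
    if (!m$effect_stem %in% rule_stems) next
    g <- gmap[[sentence_fingerprint(m$sentence)]]
    if (is.null(g)) next
    raw <- apply_rulebook(g, m, rulebook, expansion_links = config$expansion_links)
    if (is.null(raw)) next
    rel <- withCallingHandlers(
      normalize_extraction(raw, lexicon, effect_lexicon, quiet = quiet),
      upk_note = function(c) if (quiet) rlang::cnd_muffle(c)
    )
    if (nrow(rel) > 0) rels[[length(rels) + 1L]] <- rel
  }
  if (length(rels) == 0) {
    return(tibble::tibble(
      substance = character(), effect_type = character(), process = character(),
      disease = character(), body_part = character(), pmid = character(),
      sentence = character()
    ))
  }
  dplyr::distinct(dplyr::bind_rows(rels))
}

#' Run the full discovery pipeline
#'
#' Extraction ([run_extraction()]) followed by hypothesis generation
#' ([generate_hypotheses()]).
#'
#' @inheritParams run_extraction
#' @param chem a [chemical_records()] tibble or TSV path.
#' @param threshold similarity threshold for hypothesis pairs.
#' @return list with elements `relations` and `hypotheses` (both tibbles).
#' @export
run_pipeline <- function(xml_path, parse_path, rulebook, lexicon, chem,
                         effect_lexicon = default_effect_lexicon(),
                         threshold = NULL, config = upk_config(), quiet = TRUE) {
  if (is.character(chem)) chem <- read_chemical_records(chem)
  relations <- run_extraction(xml_path, parse_path, rulebook, lexicon,
                              effect_lexicon, config = config, quiet = quiet)
  hypotheses <- generate_hypotheses(relations, chem, threshold = threshold,
                                    config = config)
  list(relations = relations, hypotheses = hypotheses)
}
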