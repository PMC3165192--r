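#' Build a semantic lexicon
#'
#' The lexicon is a file-backed stand-in for a named-entity recognizer with
#' an ontology behind it: it types a surface term into one of the four
#' concept groups (SUBSTANCE, PROCESS, DISEASE, BODYPART) and attaches a
#' UMLS-style semantic type string. Lookup is surface-based (case-folded,
#' whitespace-squished), not stem-based, so entity names like "HCT-116"
#' survive intact.
#'
#' @param term character vector of terms.
#' @param group matching concept group, from the closed set.
#' @param semantic_type matching UMLS-style type strings.
#' @return tibble with columns `term`, `group`, `semantic_type`; terms are
#'   unique after case-folding.
#' @export
semantic_lexicon <- function(term, group, semantic_type) {
  groups <- c("SUBSTANCE", "PROCESS", "DISEASE", "BODYPART")
  if (!all(group %in% groups)) {
    rlang::abort(paste0("groups must be one of: ", paste(groups, collapse = ", ")))
  }
  tibble::tibble(
    term = fold_term(term), group = group, semantic_type = semantic_type
  ) |>
    dplyr::distinct(.data$term, .keep_all = TRUE)
}

fold_term <- function(x) tolower(stringr::str_squish(x))

#' Read a semantic lexicon TSV
#'
#' Format: `term<TAB>group<TAB>semantic_type`, `#` comments allowed.
#'
#' @param path file path.
#' @return a [semantic_lexicon()] tibble.
#' @export
read_semantic_lexicon <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#",
    col_names = c("term", "group", "semantic_type"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  semantic_lexicon(df$term, df$group, df$semantic_type)
}

#' Write a semantic lexicon TSV
#' @param lexicon a [semantic_lexicon()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_semantic_lexicon <- function(lexicon, path) {
  readr::write_tsv(lexicon, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Type a term against the semantic lexicon
#'
#' Exact case-folded lookup first; for multi-word terms that miss, the
#' longest known suffix is tried (dropping leading words one at a time), so
#' "tolfenamic acid" resolves through an "acid"-headed entry when the full
#' name is absent.
#'
#' @param term a single term string.
#' @param lexicon a [semantic_lexicon()] tibble.
#' @return list with `group` and `semantic_type`; group is `"UNKNOWN"`
#'   (with `NA` type) when no lookup succeeds.
#' @export
recognize_term <- function(term, lexicon) {
  t <- fold_term(term)
  words <- strsplit(t, " ", fixed = TRUE)[[1]]
  for (i in seq_along(words)) {
    cand <- paste(words[i:length(words)], collapse = " ")
    hit <- which(lexicon$term == cand)
    if (length(hit) > 0) {
      return(list(group = lexicon$group[hit[1]], semantic_type = lexicon$semantic_type[hit[1]]))
    }
  }
  list(group = "UNKNOWN", semantic_type = NA_character_)
}

#' Effect type of an effect-word stem
#'
#' @param effect_stem a stem string present in the effect lexicon.
#' @param lexicon effect lexicon tibble; defaults to
#'   [default_effect_lexicon()].
#' @return `"Increase"` or `"Reduction"`.
#' @export
effect_type <- function(effect_stem, lexicon = default_effect_lexicon()) {
  hit <- match(tolower(effect_stem), lexicon$stem)
  if (is.na(hit)) {
    rlang::abort(paste0("effect stem '", effect_stem, "' is not in the effect lexicon"))
  }
  lexicon$effect_type[hit]
}

slot_group <- c(
  "@SUBSTANCE" = "SUBSTANCE", "@SYMPTOM" = "PROCESS",
  "@DISEASE" = "DISEASE", "@BODYPART" = "BODYPART"
)
group_field <- c(
  SUBSTANCE = "substance", PROCESS = "process",
  DISEASE = "disease", BODYPART = "body_part"
)

#' Normalize a raw extraction into SEPDB relations
#'
#' Applies the recognizer contract: every bound term is typed against the
#' semantic lexicon; unknown terms are dropped; a term whose recognized
#' group disagrees with the slot it was extracted into is moved to its
#' correct slot (e.g. a disease caught by a process rule). When a moved
#' term would displace a term that natively belongs to that slot, the
#' native term wins and the moved one is dropped with a warning. Multiple
#' candidates fan out into one relation per substance x process/disease
#' context x body part, deduplicated. Assemblies violating the relation
#' invariants (substance present; at least one of process/disease present)
#' are rejected with a logged reason.
#'
#' @param raw a `raw_extraction` from [apply_rulebook()].
#' @param lexicon a [semantic_lexicon()] tibble.
#' @param effect_lexicon effect lexicon for typing the effect stem.
#' @param quiet suppress rejection/drop messages.
#' @return a tibble of relations (columns `substance`, `effect_type`,
#'   `process`, `disease`, `body_part`, `pmid`, `sentence`), possibly with
#'   zero rows.
#' @export
normalize_extraction <- function(raw, lexicon,
                                 effect_lexicon = default_effect_lexicon(),
                                 quiet = FALSE) {
  stopifnot(inherits(raw, "raw_extraction"))
  note <- function(...) if (!quiet) rlang::inform(sprintf(...), class = "upk_note")

  # type every candidate, remembering its original slot
  cand <- list()
  for (slot in names(raw$slots)) {
    for (term in raw$slots[[slot]]) {
      rec <- recognize_term(term, lexicon)
      if (rec$group == "UNKNOWN") {
        note("dropping unknown term '%s' (slot %s)", term, slot)
        next
      }
      cand[[length(cand) + 1L]] <- tibble::tibble(
        term = stringr::str_squish(term),
        original_group = unname(slot_group[slot]),
        group = rec$group
      )
    }
  }
  empty <- tibble::tibble(
    substance = character(), effect_type = character(), process = character(),
    disease = character(), body_part = character(), pmid = character(),
    sentence = character()
  )
  if (length(cand) == 0) {
    note("rejected: no recognizable term in any slot")
    return(empty)
  }
  cand <- dplyr::distinct(dplyr::bind_rows(cand))

  # slot repair + collision policy: native terms (recognized group equals
  # the slot they were extracted into) outrank moved ones
  buckets <- list()
  for (g in unique(cand$group)) {
    rows <- cand[cand$group == g, ]
    native <- rows$term[rows$original_group == g]
    moved <- rows$term[rows$original_group != g]
    if (length(native) > 0) {
      if (length(moved) > 0) {
        note("slot %s already filled; dropping moved term(s): %s",
             g, paste(setdiff(moved, native), collapse = ", "))
      }
      buckets[[g]] <- unique(native)
    } else {
      buckets[[g]] <- unique(moved)
    }
  }

  if (is.null(buckets$SUBSTANCE)) {
    note("rejected: no substance")
    return(empty)
  }
  if (is.null(buckets$PROCESS) && is.null(buckets$DISEASE)) {
    note("rejected: neither process nor disease")
    return(empty)
  }

  etype <- effect_type(raw$effect_stem, effect_lexicon)
  grid <- tidyr::expand_grid(
    substance = buckets$SUBSTANCE,
    process = buckets$PROCESS %||% NA_character_,
    disease = buckets$DISEASE %||% NA_character_,
    body_part = buckets$BODYPART %||% NA_character_
  )
  grid |>
    dplyr::mutate(
      effect_type = etype,
      pmid = raw$pmid,
      sentence = raw$sentence
    ) |>
    dplyr::select(
      "substance", "effect_type", "process", "disease", "body_part",
      "pmid", "sentence"
    ) |>
    dplyr::distinct()
}

#' Write relations to TSV
#'
#' Mirrors the standard relation-table rendering: absent fields are written
#' as `"N/A"`.
#'
#' @param relations relations tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_relations <- function(relations, path) {
  out <- dplyr::mutate(
    relations,
    dplyr::across(dplyr::any_of(c("process", "disease", "body_part")),
                  \(x) dplyr::coalesce(x, "N/A"))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a relations TSV written by [write_relations()]
#' @param path file path.
#' @return relations tibble with `"N/A"` fields restored to `NA`.
#' @export
read_relations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  dplyr::mutate(
    df,
    dplyr::across(dplyr::any_of(c("process", "disease", "body_part")),
                  \(x) dplyr::na_if(x, "N/A"))
  )
}
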