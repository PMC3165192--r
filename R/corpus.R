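#' Read MEDLINE-style abstracts
#'
#' Reads a minimal PubmedArticleSet-style XML dialect: any element named
#' `PubmedArticle` (or `Article`) anywhere in the document contributes one
#' record, taking its `PMID`, `ArticleTitle` and `AbstractText` descendants.
#' All other elements are ignored. Text is whitespace-normalized; multiple
#' `AbstractText` sections (structured abstracts) are concatenated with a
#' space.
#'
#' @param path path to an XML file.
#' @return a tibble with columns `pmid`, `title`, `abstract`, one row per
#'   article in document order.
#' @seealso [write_medline_xml()], [select_sentences()]
#' @export
read_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  articles <- xml2::xml_find_all(doc, "//PubmedArticle | //Article[not(ancestor::PubmedArticle)]")
  if (length(articles) == 0) {
    return(tibble::tibble(pmid = character(), title = character(), abstract = character()))
  }
  recs <- purrr::imap(articles, function(node, i) {
    pmid_node <- xml2::xml_find_first(node, ".//PMID")
    if (inherits(pmid_node, "xml_missing")) {
      rlang::abort(sprintf("article %d has no PMID element", i))
    }
    pmid <- stringr::str_squish(xml2::xml_text(pmid_node))
    if (pmid == "") {
      rlang::abort(sprintf("article %d has an empty PMID element", i))
    }
    title <- xml2::xml_find_first(node, ".//ArticleTitle")
    abst <- xml2::xml_find_all(node, ".//AbstractText")
    tibble::tibble(
      pmid = pmid,
      title = if (inherits(title, "xml_missing")) "" else stringr::str_squish(xml2::xml_text(title)),
      abstract = stringr::str_squish(paste(xml2::xml_text(abst), collapse = " "))
    )
  })
  out <- dplyr::bind_rows(recs)
  dup <- unique(out$pmid[duplicated(out$pmid)])
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate PMID(s) in corpus: ", paste(dup, collapse = ", ")))
  }
  out
}

#' Write abstracts as MEDLINE-style XML
#'
#' Inverse of [read_medline_xml()]; used by the synthetic corpus generator
#' and for round-trip testing.
#'
#' @param abstracts tibble with columns `pmid`, `title`, `abstract`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(abstracts, path) {
  stopifnot(all(c("pmid", "title", "abstract") %in% names(abstracts)))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<PubmedArticleSet>",
    unlist(purrr::pmap(abstracts[c("pmid", "title", "abstract")], function(pmid, title, abstract) {
      c(
        "  <PubmedArticle>",
        paste0("    <PMID>", esc(pmid), "</PMID>"),
        paste0("    <ArticleTitle>", esc(title), "</ArticleTitle>"),
        paste0("    <AbstractText>", esc(abstract), "</AbstractText>"),
        "  </PubmedArticle>"
      )
    })),
    "</PubmedArticleSet>"
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# abbreviations that never end a sentence when followed by a space
sentence_abbrev <- c(
  "e.g.", "i.e.", "et al.", "al.", "fig.", "figs.", "vs.", "cf.", "dr.",
  "no.", "approx.", "ca.", "resp.", "spp.", "sp."
)

#' Split text into sentences
#'
#' Rule-based splitter: a sentence ends at `.`, `?` or `!` followed by
#' whitespace and an upper-case letter or digit, unless the terminator
#' closes a known abbreviation (e.g., i.e., et al., Fig., vs.). Hyphens,
#' parentheses and decimal points never split. The concatenation of the
#' returned sentences equals the input up to whitespace.
#'
#' @param text a single character string (an abstract).
#' @return character vector of sentences; empty input gives `character(0)`.
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1)
  text <- stringr::str_squish(text)
  if (is.na(text) || text == "") return(character(0))
  hits <- stringr::str_locate_all(text, "[.?!](?=\\s+[A-Z0-9])")[[1]]
  cuts <- integer(0)
  for (pos in hits[, 1]) {
    prefix <- tolower(substr(text, max(1L, pos - 8L), pos))
    if (!any(vapply(sentence_abbrev, function(a) endsWith(prefix, a), logical(1)))) {
      cuts <- c(cuts, pos)
    }
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(text))
  out <- stringr::str_trim(stringr::str_sub(text, starts, ends))
  out[out != ""]
}

#' Tokenize a sentence
#'
#' Whitespace tokenization with outer punctuation stripped; internal hyphens
#' and digits are preserved so entity names like "HCT-116" stay intact.
#'
#' @param sentence a single string.
#' @return character vector of tokens.
#' @export
tokenize_words <- function(sentence) {
  toks <- stringr::str_split_1(stringr::str_squish(sentence), "\\s+")
  toks <- stringr::str_remove_all(toks, "^[^[:alnum:]]+|[^[:alnum:]]+$")
  toks[toks != ""]
}

#' The default effect lexicon
#'
#' Five effect words with their types: induce, contribute and increase mark
#' an Increase effect; reduce and resistant mark a Reduction. Words are
#' stored as Porter stems so inflected surface forms ("induces", "inducer")
#' match.
#'
#' @return a tibble with columns `stem` and `effect_type`.
#' @seealso [read_effect_lexicon()] to extend the list from a file.
#' @export
default_effect_lexicon <- function() {
  effect_lexicon(
    word = c("induce", "contribute", "reduce", "increase", "resistant"),
    type = c("Increase", "Increase", "Reduction", "Increase", "Reduction")
  )
}

#' Build an effect lexicon from words and types
#'
#' @param word character vector of effect words (surface forms; stemmed here).
#' @param type matching vector of effect types, each `"Increase"` or
#'   `"Reduction"`.
#' @return a tibble with columns `stem`, `effect_type`, one row per distinct stem.
#' @export
effect_lexicon <- function(word, type) {
  if (!all(type %in% c("Increase", "Reduction"))) {
    rlang::abort("effect types must be 'Increase' or 'Reduction'")
  }
  tibble::tibble(stem = porter_stem(word), effect_type = type) |>
    dplyr::distinct(.data$stem, .keep_all = TRUE)
}

#' Read an effect lexicon from a TSV file
#'
#' Format: two tab-separated columns `word<TAB>type`, `#` comment lines
#' allowed; words are stemmed at load time.
#'
#' @param path file path.
#' @return a tibble with columns `stem`, `effect_type`.
#' @export
read_effect_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  if (any(parts[, 2] == "")) {
    bad <- which(parts[, 2] == "")[1]
    rlang::abort(sprintf("effect lexicon: line %d is not 'word<TAB>type'", bad))
  }
  effect_lexicon(parts[, 1], parts[, 2])
}

#' Select sentences that contain an effect word
#'
#' Splits each abstract into sentences, stems every token, and keeps the
#' sentences in which some token's stem appears in the effect lexicon. One
#' row is emitted per (sentence, matching token) pair, so a sentence with
#' two distinct effect words yields two rows.
#'
#' @param abstracts tibble with columns `pmid`, `abstract` (as from
#'   [read_medline_xml()]).
#' @param lexicon effect lexicon tibble (`stem`, `effect_type`); defaults to
#'   [default_effect_lexicon()].
#' @return a tibble with columns `pmid`, `sentence`, `effect_surface`,
#'   `effect_stem`, `effect_type`.
#' @export
select_sentences <- function(abstracts, lexicon = default_effect_lexicon()) {
  stopifnot(nrow(lexicon) > 0)
  rows <- purrr::pmap(abstracts[c("pmid", "abstract")], function(pmid, abstract) {
    sents <- split_sentences(abstract)
    purrr::map(sents, function(s) {
      toks <- tokenize_words(s)
      stems <- porter_stem(toks)
      hit <- stems %in% lexicon$stem
      if (!any(hit)) return(NULL)
      tibble::tibble(
        pmid = pmid,
        sentence = s,
        effect_surface = toks[hit],
        effect_stem = stems[hit]
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    return(tibble::tibble(
      pmid = character(), sentence = character(), effect_surface = character(),
      effect_stem = character(), effect_type = character()
    ))
  }
  dplyr::left_join(out, lexicon, by = c(effect_stem = "stem"))
}
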