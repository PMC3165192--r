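# Template-based fixture linker. It is NOT a parser: it produces
# deterministic link-grammar-style graphs for sentences generated from the
# small set of surface templates below, so that the rule layer can be
# exercised without an external parsing stack.

# determiners and quantifiers attach to the entity head with a D link, which
# is outside the default entity-expansion set, so they stay out of the span
linker_determiners <- c("a", "an", "the", "several", "some", "many", "various")

# Each template is a vector of elements: literal words (matched
# case-insensitively), "@SLOT" placeholders absorbing one or more tokens,
# and "VERB" which matches any single token whose stem is in the effect
# lexicon. `links` lists the inter-element links as (from, to, label) where
# elements are referenced by position and slots by their head (last) token.
linker_templates <- function() {
  list(
    # "Tolfenamic acid induces Sp protein degradation in several cancer cell lines"
    list(
      name = "svo_pp",
      pattern = c("@X", "VERB", "@Y", "in", "@Z"),
      links = list(c(1, 2, "Ss"), c(2, 3, "Os"), c(2, 4, "MVp"), c(4, 5, "Js"))
    ),
    # "Docetaxel was a potent inducer of apoptosis"
    list(
      name = "nominal_of",
      pattern = c("@X", "was", "a", "potent", "VERB", "of", "@Y"),
      links = list(
        c(1, 2, "Ss"), c(3, 5, "Ds"), c(4, 5, "A"),
        c(2, 5, "Ost"), c(5, 6, "Mp"), c(6, 7, "Js")
      )
    ),
    # "Docetaxel was a more potent inducer of apoptosis"
    list(
      name = "nominal_of_cmp",
      pattern = c("@X", "was", "a", "more", "potent", "VERB", "of", "@Y"),
      links = list(
        c(1, 2, "Ss"), c(3, 6, "Ds"), c(4, 5, "EA"), c(5, 6, "A"),
        c(2, 6, "Ost"), c(6, 7, "Mp"), c(7, 8, "Js")
      )
    ),
    # "Fisetin reduces oxidative stress"
    list(
      name = "svo",
      pattern = c("@X", "VERB", "@Y"),
      links = list(c(1, 2, "Ss"), c(2, 3, "Os"))
    )
  )
}

#' Build a parse graph for a template sentence
#'
#' Deterministically links a sentence that was produced from one of the
#' fixture surface templates ("X induces Y in Z", "X was a potent inducer
#' of Y", "X reduces Y"). Multi-word entity slots are chained with AN links
#' (head-final); a leading determiner inside a slot attaches with a D link
#' instead, so entity expansion stops before it. Sentences that match no
#' template raise an error.
#'
#' @param sentence sentence text (trailing period allowed).
#' @param sentence_id identifier for the resulting graph; defaults to the
#'   sentence itself.
#' @param lexicon effect lexicon used to locate the effect (verb) token.
#' @return a [parse_graph()].
#' @export
toy_linker <- function(sentence, sentence_id = NULL,
                       lexicon = default_effect_lexicon()) {
  toks <- tokenize_words(sentence)
  if (length(toks) == 0) rlang::abort("empty sentence cannot be linked")
  if (is.null(sentence_id)) sentence_id <- stringr::str_squish(sentence)
  stems <- porter_stem(toks)
  for (tpl in linker_templates()) {
    m <- match_template(toks, stems, tpl, lexicon)
    if (!is.null(m)) {
      return(parse_graph(sentence_id, toks, m))
    }
  }
  rlang::abort(paste0("sentence matches no linkage template: ", sentence))
}

# returns a links data frame, or NULL when the template does not match
match_template <- function(toks, stems, tpl, lexicon) {
  n <- length(toks)
  pat <- tpl$pattern
  k <- length(pat)
  is_slot <- startsWith(pat, "@")
  is_verb <- pat == "VERB"

  # assign token ranges to pattern elements left to right; literals and VERB
  # take one token, slots absorb tokens greedily up to the next anchor
  assign_from <- function(p, t) {
    # returns list of c(start, end) per element p..k for tokens t..n, or NULL
    if (p > k) return(if (t > n) list() else NULL)
    if (!is_slot[p]) {
      if (t > n) return(NULL)
      ok <- if (is_verb[p]) stems[t] %in% lexicon$stem else tolower(toks[t]) == pat[p]
      if (!ok) return(NULL)
      rest <- assign_from(p + 1L, t + 1L)
      if (is.null(rest)) return(NULL)
      return(c(list(c(t, t)), rest))
    }
    # slot: try longest span first so entity names absorb greedily
    for (e in n:t) {
      rest <- assign_from(p + 1L, e + 1L)
      if (!is.null(rest)) return(c(list(c(t, e)), rest))
    }
    NULL
  }
  spans <- assign_from(1L, 1L)
  if (is.null(spans)) return(NULL)

  links <- list()
  add <- function(l, r, lab) {
    links[[length(links) + 1L]] <<- tibble::tibble(
      left = min(l, r) - 1L, right = max(l, r) - 1L, full_label = lab
    )
  }
  heads <- vapply(spans, function(s) s[2], numeric(1))
  # intra-slot links: determiner -> D to head, other modifiers chain with AN
  for (p in which(is_slot)) {
    s <- spans[[p]]
    if (s[1] < s[2]) {
      for (t in s[1]:(s[2] - 1L)) {
        if (t == s[1] && tolower(toks[t]) %in% linker_determiners) {
          add(t, s[2], "Dmc")
        } else {
          add(t, t + 1L, "AN")
        }
      }
    }
  }
  for (l in tpl$links) {
    add(heads[as.integer(l[[1]])], heads[as.integer(l[[2]])], l[[3]])
  }
  dplyr::bind_rows(links)
}
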