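#' Construct an extraction rule
#'
#' A rule is a path through a parse graph: starting at an effect word it
#' follows links (by reduced label and direction), optionally checking the
#' stem of each intermediate word (a "node"), and lands on a concept token
#' that fills one SEPDB placeholder.
#'
#' @param effect_stem Porter stem of the effect word the rule belongs to.
#' @param steps data frame with columns `reduced_label`, `direction`
#'   (`"+"`/`"-"`) and `node_stem` (NA on the final step, which lands on
#'   the concept).
#' @param placeholder one of `@SUBSTANCE`, `@SYMPTOM`, `@DISEASE`,
#'   `@BODYPART`.
#' @return an object of class `extraction_rule`.
#' @export
extraction_rule <- function(effect_stem, steps, placeholder) {
  steps <- tibble::as_tibble(steps[c("reduced_label", "direction", "node_stem")])
  if (nrow(steps) < 1) rlang::abort("a rule needs at least one step")
  if (!all(steps$direction %in% c("+", "-"))) {
    rlang::abort("step directions must be '+' or '-'")
  }
  if (!is.na(steps$node_stem[nrow(steps)])) {
    rlang::abort("the final step of a rule carries no node word")
  }
  if (!placeholder %in% sepdb_placeholders) {
    rlang::abort(paste0("placeholder must be one of: ", paste(sepdb_placeholders, collapse = ", ")))
  }
  structure(
    list(effect_stem = tolower(effect_stem), steps = steps, placeholder = placeholder),
    class = "extraction_rule"
  )
}

#' @export
format.extraction_rule <- function(x, ...) {
  step_txt <- purrr::map_chr(seq_len(nrow(x$steps)), function(i) {
    s <- paste0(x$steps$reduced_label[i], x$steps$direction[i])
    if (!is.na(x$steps$node_stem[i])) s <- paste0(s, " (", x$steps$node_stem[i], ")")
    s
  })
  paste(x$effect_stem, "::", paste(step_txt, collapse = " "), x$placeholder)
}

#' @export
print.extraction_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

rule_key <- function(rule) format(rule)

#' Learn extraction rules from a tagged sentence
#'
#' For each tagged concept span, the shortest undirected link path from the
#' effect token to the span's head (its rightmost token) becomes a rule:
#' each traversed link contributes a (reduced label, direction) step, each
#' intermediate token contributes its stem as the step's node word. Ties
#' between equal-length paths are broken deterministically in favour of the
#' lexicographically smallest (label, direction) step sequence.
#'
#' @param tagged a [tagged_sentence()].
#' @return list of [extraction_rule()] objects, one per tagged span.
#' @export
learn_rules <- function(tagged) {
  stopifnot(inherits(tagged, "tagged_sentence"))
  g <- tagged$graph
  effect_stem <- g$tokens$stem[tagged$effect_index + 1L]
  purrr::map(seq_len(nrow(tagged$tags)), function(i) {
    head <- tagged$tags$end[i]
    path <- shortest_link_path(g, tagged$effect_index, head)
    if (is.null(path)) {
      span <- span_text(g, c(tagged$tags$start[i], tagged$tags$end[i]))
      rlang::abort(sprintf(
        "concept '%s' (%s) is not reachable from the effect word in the link graph",
        span, tagged$tags$placeholder[i]
      ))
    }
    steps <- path$steps
    steps$node_stem[nrow(steps)] <- NA_character_
    extraction_rule(effect_stem, steps, tagged$tags$placeholder[i])
  })
}

# BFS over the undirected link graph from `from` to `to`; among equal-length
# paths the lexicographically smallest (reduced_label, direction) sequence
# wins. Returns list(steps = tibble) or NULL when unreachable.
shortest_link_path <- function(graph, from, to) {
  n <- nrow(graph$tokens)
  l <- graph$links
  # edge list both ways: from token, to token, label, direction
  ed <- dplyr::bind_rows(
    tibble::tibble(a = l$left, b = l$right, label = l$reduced_label, dir = "+"),
    tibble::tibble(a = l$right, b = l$left, label = l$reduced_label, dir = "-")
  )
  ed <- ed[order(ed$a, ed$label, ed$dir, ed$b), ]
  best_key <- rep(NA_character_, n)
  best_path <- vector("list", n)
  dist <- rep(NA_integer_, n)
  dist[from + 1L] <- 0L
  best_key[from + 1L] <- ""
  frontier <- from
  d <- 0L
  while (length(frontier) > 0 && is.na(dist[to + 1L])) {
    d <- d + 1L
    nxt <- integer(0)
    for (u in frontier) {
      rows <- which(ed$a == u)
      for (r in rows) {
        v <- ed$b[r]
        key <- paste0(best_key[u + 1L], ed$label[r], ed$dir[r], "\u01")
        if (is.na(dist[v + 1L])) {
          dist[v + 1L] <- d
          best_key[v + 1L] <- key
          best_path[[v + 1L]] <- dplyr::bind_rows(
            best_path[[u + 1L]],
            tibble::tibble(
              reduced_label = ed$label[r], direction = ed$dir[r],
              node_stem = graph$tokens$stem[v + 1L]
            )
          )
          nxt <- c(nxt, v)
        } else if (dist[v + 1L] == d && key < best_key[v + 1L]) {
          best_key[v + 1L] <- key
          best_path[[v + 1L]] <- dplyr::bind_rows(
            best_path[[u + 1L]],
            tibble::tibble(
              reduced_label = ed$label[r], direction = ed$dir[r],
              node_stem = graph$tokens$stem[v + 1L]
            )
          )
        }
      }
    }
    frontier <- sort(unique(nxt))
  }
  if (is.na(dist[to + 1L])) return(NULL)
  list(steps = best_path[[to + 1L]])
}

#' Write a rulebook file
#'
#' One rule per line: `<effect_stem> :: <LABEL><dir> [(node_stem)] ...
#' @CONCEPT`, e.g. `induc :: MV+ (of) J+ @SYMPTOM`. Duplicate rules are
#' written once; lines are sorted for reproducible files.
#'
#' @param rules list of [extraction_rule()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rulebook <- function(rules, path) {
  lines <- sort(unique(vapply(rules, rule_key, character(1))))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a rulebook file
#'
#' @param path rulebook file; `#` comment lines and blank lines allowed.
#' @return list of [extraction_rule()] objects.
#' @export
read_rulebook <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  for (i in seq_along(lines)) {
    ln <- stringr::str_trim(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    rule <- tryCatch(
      parse_rule_line(ln),
      error = function(e) rlang::abort(sprintf("rulebook line %d: %s", i, conditionMessage(e)))
    )
    out[[length(out) + 1L]] <- rule
  }
  out
}

parse_rule_line <- function(line) {
  m <- stringr::str_match(line, "^(\\S+)\\s*::\\s*(.+)$")
  if (is.na(m[1, 1])) rlang::abort("expected '<effect_stem> :: <steps> @CONCEPT'")
  effect_stem <- m[1, 2]
  toks <- stringr::str_split_1(stringr::str_trim(m[1, 3]), "\\s+")
  if (length(toks) < 2) rlang::abort("rule needs at least one step and a placeholder")
  placeholder <- toks[length(toks)]
  toks <- toks[-length(toks)]
  steps <- list()
  i <- 1L
  while (i <= length(toks)) {
    sm <- stringr::str_match(toks[i], "^([A-Z]+)([+-])$")
    if (is.na(sm[1, 1])) rlang::abort(paste0("malformed step '", toks[i], "'"))
    node <- NA_character_
    if (i < length(toks) && grepl("^\\(.+\\)$", toks[i + 1L])) {
      node <- stringr::str_sub(toks[i + 1L], 2L, -2L)
      i <- i + 1L
    }
    steps[[length(steps) + 1L]] <- tibble::tibble(
      reduced_label = sm[1, 2], direction = sm[1, 3], node_stem = node
    )
    i <- i + 1L
  }
  steps <- dplyr::bind_rows(steps)
  if (!is.na(steps$node_stem[nrow(steps)])) {
    rlang::abort("the final step must not carry a node word")
  }
  extraction_rule(effect_stem, steps, placeholder)
}

#' Match one rule against a parse graph
#'
#' Traverses the rule's steps starting from the effect token, following
#' every link of the required reduced label in the required direction and
#' filtering by node stem where the rule specifies one. Every token the
#' full route reaches is expanded into an entity span. An incomplete route
#' is a non-match (empty result), not an error.
#'
#' @param graph a [parse_graph()].
#' @param effect_index 0-based index of the effect token; its stem must
#'   equal the rule's effect stem.
#' @param rule an [extraction_rule()].
#' @param expansion_links passed to [expand_entity()].
#' @return list of integer spans `c(start, end)`, deduplicated.
#' @export
match_rule <- function(graph, effect_index, rule,
                       expansion_links = c("AN", "A", "G")) {
  stopifnot(inherits(graph, "parse_graph"), inherits(rule, "extraction_rule"))
  effect_index <- as.integer(effect_index)
  if (graph$tokens$stem[effect_index + 1L] != rule$effect_stem) {
    rlang::abort("effect token stem does not match the rule's effect stem")
  }
  current <- effect_index
  for (i in seq_len(nrow(rule$steps))) {
    nxt <- integer(0)
    for (u in current) {
      nxt <- c(nxt, graph_neighbors(graph, u, rule$steps$reduced_label[i],
                                    rule$steps$direction[i]))
    }
    nxt <- sort(unique(nxt))
    if (!is.na(rule$steps$node_stem[i])) {
      nxt <- nxt[graph$tokens$stem[nxt + 1L] == rule$steps$node_stem[i]]
    }
    if (length(nxt) == 0) return(list())
    current <- nxt
  }
  spans <- purrr::map(current, function(t) expand_entity(graph, t, expansion_links))
  unique(spans)
}

#' Apply a rulebook to one selected sentence
#'
#' Runs every rule whose effect stem matches the sentence's effect word and
#' aggregates the bound spans per placeholder (deduplicated). Returns
#' `NULL` when no placeholder binds at all.
#'
#' @param graph parse graph of the sentence.
#' @param match one row of [select_sentences()] output (list or one-row
#'   tibble with `pmid`, `sentence`, `effect_surface`, `effect_stem`).
#' @param rulebook list of [extraction_rule()] objects.
#' @param expansion_links passed to [expand_entity()].
#' @return a `raw_extraction` object: provenance fields plus `slots`, a
#'   named list mapping placeholders to character vectors of span texts; or
#'   `NULL`.
#' @export
apply_rulebook <- function(graph, match, rulebook,
                           expansion_links = c("AN", "A", "G")) {
  match <- as.list(match)
  rules <- rulebook[vapply(rulebook, function(r) r$effect_stem == match$effect_stem, logical(1))]
  if (length(rules) == 0) {
    rlang::abort(paste0("no rule in the rulebook for effect stem '", match$effect_stem, "'"))
  }
  anchors <- graph$tokens$index[graph$tokens$stem == match$effect_stem]
  slots <- list()
  for (rule in rules) {
    for (at in anchors) {
      for (span in match_rule(graph, at, rule, expansion_links)) {
        txt <- span_text(graph, span)
        slots[[rule$placeholder]] <- unique(c(slots[[rule$placeholder]], txt))
      }
    }
  }
  if (length(slots) == 0) return(NULL)
  structure(
    list(
      pmid = match$pmid %||% NA_character_,
      sentence = match$sentence %||% NA_character_,
      effect_surface = match$effect_surface %||% NA_character_,
      effect_stem = match$effect_stem,
      slots = slots
    ),
    class = "raw_extraction"
  )
}

#' @export
print.raw_extraction <- function(x, ...) {
  cat("<raw_extraction>", x$effect_stem, "\n")
  for (p in names(x$slots)) cat(" ", p, "=", paste(x$slots[[p]], collapse = " | "), "\n")
  invisible(x)
}
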