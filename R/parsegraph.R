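#' Construct a parse graph
#'
#' A parse graph represents one sentence the way a link-grammar parse does:
#' words are vertices, typed links are edges. Links are stored with
#' `left < right` (token indices are 0-based sentence positions); the
#' traversal direction (`+` right, `-` left) is resolved relative to the
#' token a rule is standing on.
#'
#' @param sentence_id identifier string for the sentence.
#' @param tokens character vector of surface tokens, in sentence order.
#' @param links data frame with columns `left`, `right` (0-based token
#'   indices) and `full_label` (e.g. `"Ss"`); may have zero rows.
#' @return an object of class `parse_graph` with fields `sentence_id`,
#'   `tokens` (tibble: `index`, `surface`, `stem`) and `links` (tibble:
#'   `left`, `right`, `full_label`, `reduced_label`).
#' @export
parse_graph <- function(sentence_id, tokens, links = NULL) {
  n <- length(tokens)
  tok <- tibble::tibble(
    index = seq_len(n) - 1L,
    surface = as.character(tokens),
    stem = porter_stem(tokens)
  )
  if (is.null(links) || nrow(links) == 0) {
    lnk <- tibble::tibble(
      left = integer(), right = integer(),
      full_label = character(), reduced_label = character()
    )
  } else {
    lnk <- tibble::as_tibble(links[c("left", "right", "full_label")])
    lnk$left <- as.integer(lnk$left)
    lnk$right <- as.integer(lnk$right)
    if (any(lnk$left >= lnk$right)) {
      rlang::abort("parse links must have left < right")
    }
    if (any(lnk$left < 0L | lnk$right >= n)) {
      rlang::abort("parse link refers to an out-of-range token index")
    }
    lnk$reduced_label <- reduce_label(lnk$full_label)
    lnk <- dplyr::distinct(lnk, .data$left, .data$right, .data$full_label, .keep_all = TRUE)
  }
  structure(
    list(sentence_id = as.character(sentence_id), tokens = tok, links = lnk),
    class = "parse_graph"
  )
}

#' @export
print.parse_graph <- function(x, ...) {
  cat("<parse_graph>", x$sentence_id, "\n")
  cat(" ", paste(x$tokens$surface, collapse = " "), "\n")
  if (nrow(x$links) > 0) {
    cat(sprintf(
      "  %d links: %s\n", nrow(x$links),
      paste(sprintf("%d-%s-%d", x$links$left, x$links$full_label, x$links$right), collapse = " ")
    ))
  }
  invisible(x)
}

#' Reduce a link label to its primary form
#'
#' Link-grammar labels carry an upper-case primary type plus lower-case
#' subscripts ("Ss", "MVp"). Rules store and match only the primary part,
#' so subscript variants of the same link satisfy the same rule.
#'
#' @param full_label character vector of link labels.
#' @return character vector of reduced labels (leading upper-case letters).
#' @examples
#' reduce_label(c("S", "Ss", "MVp"))
#' @export
reduce_label <- function(full_label) {
  out <- stringr::str_extract(full_label, "^[A-Z]+")
  bad <- is.na(out) | full_label == ""
  if (any(bad)) {
    rlang::abort(paste0(
      "link label(s) without an upper-case primary part: ",
      paste(unique(full_label[bad]), collapse = ", ")
    ))
  }
  out
}

#' Tag a parsed sentence for rule learning
#'
#' A tagged sentence is the training unit for rule learning: the effect
#' token plus one or more concept spans labelled with SEPDB placeholders.
#'
#' @param graph a [parse_graph()].
#' @param effect_index 0-based index of the effect token.
#' @param tags data frame with columns `start`, `end` (0-based, closed
#'   span) and `placeholder` (one of `@SUBSTANCE`, `@SYMPTOM`, `@DISEASE`,
#'   `@BODYPART`).
#' @param lexicon effect lexicon used to validate the effect token.
#' @return an object of class `tagged_sentence`.
#' @export
tagged_sentence <- function(graph, effect_index, tags,
                            lexicon = default_effect_lexicon()) {
  stopifnot(inherits(graph, "parse_graph"))
  effect_index <- as.integer(effect_index)
  n <- nrow(graph$tokens)
  if (effect_index < 0L || effect_index >= n) {
    rlang::abort("effect_index out of range")
  }
  stem <- graph$tokens$stem[effect_index + 1L]
  if (!stem %in% lexicon$stem) {
    rlang::abort(sprintf("effect token '%s' (stem '%s') is not in the effect lexicon",
                         graph$tokens$surface[effect_index + 1L], stem))
  }
  tags <- tibble::as_tibble(tags[c("start", "end", "placeholder")])
  tags$start <- as.integer(tags$start)
  tags$end <- as.integer(tags$end)
  if (!all(tags$placeholder %in% sepdb_placeholders)) {
    rlang::abort(paste0("placeholders must be one of: ", paste(sepdb_placeholders, collapse = ", ")))
  }
  if (any(tags$start > tags$end | tags$start < 0L | tags$end >= n)) {
    rlang::abort("tag span out of range")
  }
  if (any(tags$start <= effect_index & effect_index <= tags$end)) {
    rlang::abort("a concept tag overlaps the effect token")
  }
  structure(
    list(graph = graph, effect_index = effect_index, tags = tags),
    class = "tagged_sentence"
  )
}

sepdb_placeholders <- c("@SUBSTANCE", "@SYMPTOM", "@DISEASE", "@BODYPART")

#' @export
print.tagged_sentence <- function(x, ...) {
  cat("<tagged_sentence>", x$graph$sentence_id, "\n")
  cat("  effect:", x$graph$tokens$surface[x$effect_index + 1L], "\n")
  for (i in seq_len(nrow(x$tags))) {
    span <- x$graph$tokens$surface[(x$tags$start[i] + 1L):(x$tags$end[i] + 1L)]
    cat(" ", x$tags$placeholder[i], "=", paste(span, collapse = " "), "\n")
  }
  invisible(x)
}

#' Read parse graphs from an interchange file
#'
#' The line-based format replaces an external parser: one block per
#' sentence, `S <sentence_id>` header, `W <index> <surface>` per token,
#' `L <left> <right> <full_label>` per link, and optionally `E <index>`
#' (effect token) plus `T <start> <end> <PLACEHOLDER>` (concept tags) for
#' training blocks. Blocks are separated by blank lines; `#` starts a
#' comment line.
#'
#' @param path file path.
#' @param lexicon effect lexicon, used to validate `E` lines.
#' @return a list of [parse_graph()] and/or [tagged_sentence()] objects, in
#'   file order.
#' @export
read_parse_file <- function(path, lexicon = default_effect_lexicon()) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(stringr::str_trim(lines), "#")
  blocks <- split(seq_along(lines)[keep], cumsum(stringr::str_trim(lines) == "")[keep])
  out <- list()
  bno <- 0L
  for (idx in blocks) {
    idx <- idx[stringr::str_trim(lines[idx]) != ""]
    if (length(idx) == 0) next
    bno <- bno + 1L
    out[[bno]] <- parse_block(lines, idx, bno, lexicon)
  }
  out
}

parse_block <- function(lines, idx, bno, lexicon) {
  ferr <- function(i, msg) {
    rlang::abort(sprintf("parse file block %d, line %d: %s", bno, i, msg))
  }
  sid <- NULL
  words <- list()
  links <- list()
  effect <- NULL
  tags <- list()
  for (i in idx) {
    f <- stringr::str_split_1(stringr::str_trim(lines[i]), "\\s+")
    switch(f[1],
      S = {
        if (length(f) < 2) ferr(i, "S line needs a sentence id")
        sid <- f[2]
      },
      W = {
        if (length(f) < 3) ferr(i, "W line needs <index> <surface>")
        words[[length(words) + 1L]] <- list(index = as.integer(f[2]), surface = f[3])
      },
      L = {
        if (length(f) < 4) ferr(i, "L line needs <left> <right> <label>")
        links[[length(links) + 1L]] <-
          list(left = as.integer(f[2]), right = as.integer(f[3]), full_label = f[4], line = i)
      },
      E = {
        if (length(f) < 2) ferr(i, "E line needs <index>")
        effect <- as.integer(f[2])
      },
      T = {
        if (length(f) < 4) ferr(i, "T line needs <start> <end> <PLACEHOLDER>")
        tags[[length(tags) + 1L]] <-
          list(start = as.integer(f[2]), end = as.integer(f[3]), placeholder = f[4])
      },
      ferr(i, paste0("unknown record type '", f[1], "'"))
    )
  }
  if (is.null(sid)) ferr(idx[1], "block has no S header")
  wi <- vapply(words, function(w) w$index, integer(1))
  if (!identical(sort(wi), seq_along(wi) - 1L)) {
    ferr(idx[1], "token indices are not consecutive from 0")
  }
  surfaces <- character(length(wi))
  surfaces[wi + 1L] <- vapply(words, function(w) w$surface, character(1))
  n <- length(surfaces)
  for (l in links) {
    if (l$left < 0L || l$right >= n || l$left >= l$right) {
      ferr(l$line, sprintf("link %d-%d out of range for %d tokens", l$left, l$right, n))
    }
  }
  ldf <- if (length(links) == 0) NULL else {
    tibble::tibble(
      left = vapply(links, `[[`, integer(1), "left"),
      right = vapply(links, `[[`, integer(1), "right"),
      full_label = vapply(links, `[[`, character(1), "full_label")
    )
  }
  g <- parse_graph(sid, surfaces, ldf)
  if (is.null(effect)) return(g)
  tdf <- tibble::tibble(
    start = vapply(tags, `[[`, integer(1), "start"),
    end = vapply(tags, `[[`, integer(1), "end"),
    placeholder = vapply(tags, `[[`, character(1), "placeholder")
  )
  tagged_sentence(g, effect, tdf, lexicon = lexicon)
}

#' Write parse graphs to an interchange file
#'
#' @param graphs a list of [parse_graph()] / [tagged_sentence()] objects, or
#'   a single one.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parse_file <- function(graphs, path) {
  if (inherits(graphs, c("parse_graph", "tagged_sentence"))) graphs <- list(graphs)
  blocks <- purrr::map(graphs, function(x) {
    ts <- NULL
    if (inherits(x, "tagged_sentence")) {
      ts <- x
      x <- x$graph
    }
    b <- c(
      paste("S", x$sentence_id),
      sprintf("W %d %s", x$tokens$index, x$tokens$surface),
      if (nrow(x$links) > 0) sprintf("L %d %d %s", x$links$left, x$links$right, x$links$full_label)
    )
    if (!is.null(ts)) {
      b <- c(
        b,
        sprintf("E %d", ts$effect_index),
        if (nrow(ts$tags) > 0) sprintf("T %d %d %s", ts$tags$start, ts$tags$end, ts$tags$placeholder)
      )
    }
    c(b, "")
  })
  writeLines(as.character(unlist(blocks)), path, useBytes = TRUE)
  invisible(path)
}

#' Link neighbours of a token
#'
#' Returns the tokens reachable from `at` over one link of the given
#' reduced label, in the given direction: `"-"` follows links arriving from
#' the left (returns their left endpoints), `"+"` follows links leaving to
#' the right.
#'
#' @param graph a [parse_graph()].
#' @param at 0-based token index.
#' @param label reduced link label (e.g. `"S"`).
#' @param direction `"+"` (rightward) or `"-"` (leftward).
#' @return integer vector of 0-based token indices (possibly empty), sorted.
#' @export
graph_neighbors <- function(graph, at, label, direction) {
  stopifnot(inherits(graph, "parse_graph"), direction %in% c("+", "-"))
  at <- as.integer(at)
  if (at < 0L || at >= nrow(graph$tokens)) rlang::abort("token index out of range")
  l <- graph$links
  if (direction == "-") {
    sort(l$left[l$right == at & l$reduced_label == label])
  } else {
    sort(l$right[l$left == at & l$reduced_label == label])
  }
}

#' Expand an entity name leftward from its head token
#'
#' Multi-word entity names ("tolfenamic acid", "HCT-116 cells") are linked
#' head-finally through noun-modifier links. Starting at the head, the span
#' is grown leftward while the adjacent token connects into the current
#' span through a link whose reduced label is in `expansion_links`.
#'
#' @param graph a [parse_graph()].
#' @param head 0-based index of the entity head token.
#' @param expansion_links reduced labels that join entity words; default
#'   `c("AN", "A", "G")` (noun-modifier, adjective, proper-name chains).
#' @return integer vector `c(start, end)` of the 0-based closed span;
#'   always contains `head`.
#' @export
expand_entity <- function(graph, head, expansion_links = c("AN", "A", "G")) {
  stopifnot(inherits(graph, "parse_graph"))
  head <- as.integer(head)
  if (head < 0L || head >= nrow(graph$tokens)) rlang::abort("token index out of range")
  l <- graph$links
  start <- head
  while (start > 0L) {
    joins <- any(
      l$left == start - 1L & l$right >= start & l$right <= head &
        l$reduced_label %in% expansion_links
    )
    if (!joins) break
    start <- start - 1L
  }
  c(start, head)
}

span_text <- function(graph, span) {
  paste(graph$tokens$surface[(span[1] + 1L):(span[2] + 1L)], collapse = " ")
}
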