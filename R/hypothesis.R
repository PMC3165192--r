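norm_field <- function(x) {
  out <- tolower(stringr::str_squish(dplyr::coalesce(x, "N/A")))
  ifelse(out %in% c("n/a", ""), "n/a", out)
}

relation_key <- function(relations) {
  paste(
    norm_field(relations$substance), tolower(relations$effect_type),
    norm_field(relations$process), norm_field(relations$disease),
    norm_field(relations$body_part),
    sep = "\u01"
  )
}

#' Candidate substance pairs for hypothesis generation
#'
#' Considers every unordered pair of extracted relations with distinct
#' substances and the same effect type, scores the substance pair with the
#' four-component similarity, and keeps pairs whose total reaches the
#' threshold. Substances without a chemical record are skipped with a
#' warning.
#'
#' @param relations relations tibble (as from [normalize_extraction()] /
#'   [read_relations()]).
#' @param chem a [chemical_records()] tibble; names matched to substances
#'   case-insensitively after whitespace normalization.
#' @param threshold minimum similarity total (default from `config`,
#'   normally 2).
#' @param structural optional tibble (`name_a`, `name_b`, `t`, and
#'   optionally `substructure`) of precomputed structural similarities,
#'   e.g. values printed by a reference structure tool; pairs not listed
#'   fall back to SMILES-based computation.
#' @param config a [upk_config()] list.
#' @return tibble with one row per retained pair: `r1`, `r2` (row indices
#'   into `relations`), `substance_a`, `substance_b`, `score`, and
#'   `breakdown` (list column of `upk_similarity` objects).
#' @export
candidate_pairs <- function(relations, chem, threshold = NULL,
                            structural = NULL, config = upk_config()) {
  threshold <- threshold %||% config$score_threshold
  stopifnot(threshold >= 0, threshold <= 4)
  n <- nrow(relations)
  empty <- tibble::tibble(
    r1 = integer(), r2 = integer(), substance_a = character(),
    substance_b = character(), score = numeric(), breakdown = list()
  )
  if (n < 2) return(empty)

  chem_key <- fold_term(chem$name)
  rel_key <- fold_term(relations$substance)

  struct_lookup <- function(na, nb) {
    if (is.null(structural)) return(NULL)
    sa <- fold_term(structural$name_a)
    sb <- fold_term(structural$name_b)
    hit <- which((sa == na & sb == nb) | (sa == nb & sb == na))
    if (length(hit) == 0) return(NULL)
    list(
      t = structural$t[hit[1]],
      substructure = "substructure" %in% names(structural) &&
        isTRUE(structural$substructure[hit[1]])
    )
  }

  sim_cache <- list()
  pair_sim <- function(na, nb) {
    key <- paste(sort(c(na, nb)), collapse = "\u01")
    if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
    ia <- match(na, chem_key)
    ib <- match(nb, chem_key)
    if (is.na(ia) || is.na(ib)) {
      missing <- c(na, nb)[c(is.na(ia), is.na(ib))]
      rlang::warn(paste0("no chemical record for: ", paste(missing, collapse = ", "),
                         "; pair skipped"),
                  class = "upk_missing_chem")
      sim_cache[[key]] <<- list(skip = TRUE)
      return(sim_cache[[key]])
    }
    ov <- struct_lookup(na, nb)
    sim <- if (is.null(ov)) {
      similarity_score(chem[ia, ], chem[ib, ], config = config)
    } else {
      similarity_score(chem[ia, ], chem[ib, ],
                       structural_similarity = ov$t, substructure = ov$substructure,
                       config = config)
    }
    sim_cache[[key]] <- list(skip = FALSE, sim = sim)
    sim_cache[[key]]
  }

  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (rel_key[i] == rel_key[j]) next
      if (relations$effect_type[i] != relations$effect_type[j]) next
      res <- pair_sim(rel_key[i], rel_key[j])
      if (res$skip) next
      if (res$sim$total < threshold) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        r1 = i, r2 = j,
        substance_a = relations$substance[i],
        substance_b = relations$substance[j],
        score = res$sim$total,
        breakdown = list(res$sim)
      )
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::bind_rows(rows)
}

#' Recombine relation contexts into hypotheses
#'
#' For each candidate pair, two hypotheses are proposed: the first
#' relation's substance and effect type with the second relation's full
#' (process, disease, body part) context, and the converse. Candidates that
#' replicate their own parent or any extracted relation are dropped (the
#' novelty contract). When the same five-field hypothesis arises from
#' several partners, the highest pair score is kept.
#'
#' @param pairs output of [candidate_pairs()].
#' @param relations the extracted relations the pairs came from.
#' @return hypotheses tibble: `substance`, `effect_type`, `process`,
#'   `disease`, `body_part`, `score`, `partner_substance`, `sources`
#'   (parent row indices, `"r<i>+r<j>"`).
#' @export
recombine <- function(pairs, relations) {
  extracted_keys <- relation_key(relations)
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$r1[k]
    j <- pairs$r2[k]
    src <- sprintf("r%d+r%d", i, j)
    for (ord in list(c(i, j), c(j, i))) {
      h <- tibble::tibble(
        substance = relations$substance[ord[1]],
        effect_type = relations$effect_type[ord[1]],
        process = relations$process[ord[2]],
        disease = relations$disease[ord[2]],
        body_part = relations$body_part[ord[2]],
        score = pairs$score[k],
        partner_substance = relations$substance[ord[2]],
        sources = src
      )
      if (relation_key(h) %in% extracted_keys) next
      out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      substance = character(), effect_type = character(), process = character(),
      disease = character(), body_part = character(), score = numeric(),
      partner_substance = character(), sources = character()
    ))
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(.key = relation_key(dplyr::pick(dplyr::everything()))) |>
    dplyr::group_by(.data$.key) |>
    dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".key")
}

#' Rank hypotheses
#'
#' Descending by score; ties broken lexicographically by substance,
#' process, disease and body part, so the order is deterministic for any
#' input permutation.
#'
#' @param hypotheses hypotheses tibble from [recombine()].
#' @return the same tibble, reordered.
#' @export
rank_hypotheses <- function(hypotheses) {
  hypotheses |>
    dplyr::arrange(
      dplyr::desc(.data$score),
      norm_field(.data$substance), norm_field(.data$process),
      norm_field(.data$disease), norm_field(.data$body_part)
    )
}

#' Generate ranked hypotheses from extracted relations
#'
#' Convenience wrapper: [candidate_pairs()] then [recombine()] then
#' [rank_hypotheses()].
#'
#' @inheritParams candidate_pairs
#' @return ranked hypotheses tibble.
#' @export
generate_hypotheses <- function(relations, chem, threshold = NULL,
                                structural = NULL, config = upk_config()) {
  pairs <- candidate_pairs(relations, chem, threshold = threshold,
                           structural = structural, config = config)
  if (nrow(pairs) == 0) {
    return(recombine(pairs, relations))
  }
  rank_hypotheses(recombine(pairs, relations))
}

#' Write hypotheses to TSV
#'
#' Absent context fields are rendered `"N/A"`.
#'
#' @param hypotheses hypotheses tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypotheses <- function(hypotheses, path) {
  out <- dplyr::mutate(
    hypotheses,
    dplyr::across(dplyr::any_of(c("process", "disease", "body_part")),
                  \(x) dplyr::coalesce(x, "N/A"))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Dot plot of ranked hypothesis scores
#' @param hypotheses ranked hypotheses tibble.
#' @return a ggplot object.
#' @export
plot_hypotheses <- function(hypotheses) {
  df <- rank_hypotheses(hypotheses)
  df$label <- paste(
    df$substance, "→",
    dplyr::coalesce(df$process, df$disease),
    ifelse(is.na(df$body_part), "", paste0(" (", df$body_part, ")"))
  )
  df$label <- factor(df$label, levels = rev(unique(df$label)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$label)) +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::xlim(0, 4) +
    ggplot2::labs(x = "pair similarity score", y = NULL)
}
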