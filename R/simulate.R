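# Synthetic corpus generator with planted ground truth, plus the
# precision/recall evaluation used to score extraction against it.

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sim_processes <- c(
  "apoptosis", "autophagy", "angiogenesis", "oxidative stress",
  "DNA fragmentation", "caspase activation", "cell migration", "glycolysis"
)
sim_diseases <- c(
  "leukemia", "melanoma", "glioblastoma", "colon carcinoma", "lymphoma",
  "hepatitis"
)
sim_bodyparts <- c(
  "HCT-116 cells", "hepatocytes", "T lymphocytes", "bone marrow",
  "colon epithelium", "tumor cells"
)
sim_verbs <- tibble::tibble(
  surface = c("induces", "increases", "reduces"),
  effect_type = c("Increase", "Increase", "Reduction")
)
sim_scaffolds <- tibble::tibble(
  smiles = c("c1ccccc1", "C1CCNCC1", "c1ccncc1", "C1CCOC1", "C1CCCCC1"),
  xlogp_base = c(2.1, 0.4, 1.2, -0.6, 3.0)
)
sim_subst_prefixes <- c("vera", "dolo", "mira", "cepha", "lora",
                        "quina", "xylo", "fena", "bruta", "cora")
sim_subst_suffixes <- c("tine", "zole", "micin", "parib", "fenac",
                        "stat", "dipine", "olol", "sartan", "prazole")

sim_valence <- c(B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
                 F = 1L, Cl = 1L, Br = 1L, I = 1L)

# Hill-style formula with implicit hydrogens estimated from standard
# valences (aromatic atoms spend one extra valence on the ring system)
formula_from_smiles <- function(smiles) {
  g <- parse_smiles(smiles)
  deg <- rep(0L, n_atoms(g))
  for (r in seq_len(nrow(g$bonds))) {
    deg[g$bonds[r, 1]] <- deg[g$bonds[r, 1]] + 1L
    deg[g$bonds[r, 2]] <- deg[g$bonds[r, 2]] + 1L
  }
  h <- pmax(0L, sim_valence[g$atoms$element] - deg - as.integer(g$atoms$aromatic))
  counts <- table(g$atoms$element)
  counts <- c(counts, H = sum(h))
  counts <- counts[counts > 0]
  elems <- names(counts)
  hill <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  paste0(hill, ifelse(counts[hill] > 1, counts[hill], ""), collapse = "")
}

# substance table generated in pairs; a `similar_fraction` of the pairs
# share a scaffold (one member is the other plus one appended carbon, so
# the smaller maps completely into the larger), matching semantic types and
# close XLogP -- known positives for the similarity stage
sim_substances <- function(n_pairs, similar_fraction) {
  combos <- expand.grid(p = sim_subst_prefixes, s = sim_subst_suffixes,
                        stringsAsFactors = FALSE)
  names_pool <- paste0(combos$p, combos$s)
  names_pool <- names_pool[sample.int(length(names_pool))]
  if (2 * n_pairs > length(names_pool)) {
    names_pool <- paste0(rep(names_pool, each = 26), rep(letters, times = length(names_pool)))
  }
  types <- c("Organic Chemical", "Pharmacologic Substance")
  rows <- list()
  for (p in seq_len(n_pairs)) {
    scaf <- sim_scaffolds[((p - 1L) %% nrow(sim_scaffolds)) + 1L, ]
    similar <- p <= round(n_pairs * similar_fraction)
    base_sub <- c("CC", "OCC", "NCC", "CCC")[((p - 1L) %% 4L) + 1L]
    sm_a <- paste0(base_sub, scaf$smiles)
    if (similar) {
      sm_b <- paste0(sm_a, "C")
      type_b <- types[(p %% 2L) + 1L]
      type_a <- type_b
      x_a <- scaf$xlogp_base + round(stats::runif(1, -0.2, 0.2), 2)
      x_b <- x_a + round(stats::runif(1, -0.35, 0.35), 2)
    } else {
      other <- sim_scaffolds[(p %% nrow(sim_scaffolds)) + 1L, ]
      sm_b <- paste0("CCCC", other$smiles)
      type_a <- types[(p %% 2L) + 1L]
      type_b <- types[((p + 1L) %% 2L) + 1L]
      x_a <- scaf$xlogp_base + round(stats::runif(1, -0.2, 0.2), 2)
      x_b <- x_a + 1.5 + round(stats::runif(1, 0, 0.5), 2)
    }
    nm <- stringr::str_to_title(names_pool[c(2L * p - 1L, 2L * p)])
    rows[[p]] <- tibble::tibble(
      name = nm,
      semantic_type = c(type_a, type_b),
      smiles = c(sm_a, sm_b),
      formula = c(formula_from_smiles(sm_a), formula_from_smiles(sm_b)),
      xlogp = round(c(x_a, x_b), 2),
      pair = p,
      similar = similar
    )
  }
  dplyr::bind_rows(rows)
}

# realize one planted relation as a template sentence; returns the sentence
# plus the slot layout needed for a tagged training block
sim_sentence <- function(substance, verb, object, body_part) {
  if (verb == "nominal") {
    words <- c(substance, "was", "a", "potent", "inducer", "of",
               tokenize_words(object))
    effect_idx <- 4L
    obj_start <- 6L
    bp_span <- NULL
  } else if (!is.na(body_part)) {
    otoks <- tokenize_words(object)
    btoks <- tokenize_words(body_part)
    words <- c(substance, verb, otoks, "in", btoks)
    effect_idx <- 1L
    obj_start <- 2L
    bp_start <- 2L + length(otoks) + 1L            # 0-based, after "in"
    bp_span <- c(bp_start, bp_start + length(btoks) - 1L)
  } else {
    otoks <- tokenize_words(object)
    words <- c(substance, verb, otoks)
    effect_idx <- 1L
    obj_start <- 2L
    bp_span <- NULL
  }
  obj_len <- length(tokenize_words(object))
  list(
    text = paste0(paste(words, collapse = " "), "."),
    effect_index = effect_idx,                          # 0-based
    sub_span = c(0L, 0L),
    obj_span = c(obj_start, obj_start + obj_len - 1L),
    bp_span = bp_span
  )
}

#' Generate a synthetic corpus with planted relations
#'
#' Emulates every input the pipeline needs, with known ground truth:
#' MEDLINE-style abstracts whose sentences realize planted SEPDB relations
#' through a small set of surface templates ("X induces Y in Z", "X was a
#' potent inducer of Y", "X reduces Y"); parse graphs from [toy_linker()];
#' tagged training blocks (one per verb/template combination) from which
#' rules can be learned; a semantic lexicon covering the planted
#' vocabulary; and a chemical-record table in which a tunable fraction of
#' substance pairs is engineered to be similar (shared scaffold, formula
#' perturbation under the atomic threshold, XLogP jitter within 0.5), so
#' the hypothesis stage has known positives. Regeneration with the same
#' seed is byte-identical.
#'
#' Noise adds distractor sentences: half contain no effect word, half
#' contain an effect word with an out-of-lexicon substance (rejected by the
#' recognizer). Planted sentences are never corrupted.
#'
#' @param seed integer random seed; all randomness derives from it.
#' @param n_relations number of planted relations.
#' @param noise_rate distractor sentences as a fraction of `n_relations`.
#' @param dir output directory (created if needed).
#' @param similar_fraction fraction of substance pairs engineered similar.
#' @return an object of class `planted_corpus`: `paths` (named list: `xml`,
#'   `parses`, `tagged`, `lexicon`, `chem`, `truth`), `truth` (relations
#'   tibble), `chem`, `lexicon`, `seed` and the generation parameters.
#' @export
generate_corpus <- function(seed, n_relations, noise_rate = 0,
                            dir = tempfile("planted_corpus_"),
                            similar_fraction = 0.5) {
  stopifnot(n_relations >= 0, noise_rate >= 0, noise_rate <= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_local_seed(seed, {
    n_pairs <- max(2L, ceiling(n_relations / 4))
    subs <- sim_substances(n_pairs, similar_fraction)

    planted <- list()
    sentences <- list()
    tagged_keys <- character(0)
    tagged_blocks <- list()
    if (n_relations > 0) {
      for (i in seq_len(n_relations)) {
        # both members of a substance pair get the same verb so similar
        # pairs share an effect type
        pair_id <- ((i - 1L) %/% 2L) %% n_pairs + 1L
        member <- (i - 1L) %% 2L + 1L
        srow <- subs[subs$pair == pair_id, ][member, ]
        verb_row <- sim_verbs[(pair_id - 1L) %% nrow(sim_verbs) + 1L, ]
        use_nominal <- verb_row$surface == "induces" && stats::runif(1) < 0.25
        is_disease <- stats::runif(1) < 0.3
        object <- if (is_disease) {
          sim_diseases[sample.int(length(sim_diseases), 1)]
        } else {
          sim_processes[sample.int(length(sim_processes), 1)]
        }
        body_part <- if (!use_nominal && stats::runif(1) < 0.7) {
          sim_bodyparts[sample.int(length(sim_bodyparts), 1)]
        } else {
          NA_character_
        }
        verb <- if (use_nominal) "nominal" else verb_row$surface
        sent <- sim_sentence(srow$name, verb, object, body_part)
        planted[[i]] <- tibble::tibble(
          substance = srow$name,
          effect_type = verb_row$effect_type,
          process = if (is_disease) NA_character_ else object,
          disease = if (is_disease) object else NA_character_,
          body_part = body_part
        )
        sentences[[i]] <- sent

        # first occurrence of each (effect stem, template shape) becomes a
        # tagged training block
        key <- paste(verb, is.null(sent$bp_span))
        if (!key %in% tagged_keys) {
          tagged_keys <- c(tagged_keys, key)
          g <- toy_linker(sent$text, sentence_id = sprintf("train%03d", length(tagged_keys)))
          tags <- dplyr::bind_rows(
            tibble::tibble(start = sent$sub_span[1], end = sent$sub_span[2],
                           placeholder = "@SUBSTANCE"),
            tibble::tibble(start = sent$obj_span[1], end = sent$obj_span[2],
                           placeholder = "@SYMPTOM"),
            if (!is.null(sent$bp_span)) {
              tibble::tibble(start = sent$bp_span[1], end = sent$bp_span[2],
                             placeholder = "@BODYPART")
            }
          )
          tagged_blocks[[length(tagged_blocks) + 1L]] <-
            tagged_sentence(g, sent$effect_index, tags)
        }
      }
    }
    truth <- if (n_relations > 0) dplyr::bind_rows(planted) else {
      tibble::tibble(substance = character(), effect_type = character(),
                     process = character(), disease = character(),
                     body_part = character())
    }

    # distractors: plain sentences and effect sentences with unknown substances
    n_noise <- round(noise_rate * n_relations)
    noise_sents <- character(0)
    if (n_noise > 0) {
      for (k in seq_len(n_noise)) {
        if (k %% 2L == 1L) {
          noise_sents <- c(noise_sents, sprintf(
            "The study enrolled %d patients over %d months.",
            sample.int(200, 1), sample.int(36, 1)
          ))
        } else {
          proc <- sim_processes[sample.int(length(sim_processes), 1)]
          bp <- sim_bodyparts[sample.int(length(sim_bodyparts), 1)]
          noise_sents <- c(noise_sents, sprintf(
            "Qqz%dvex induces %s in %s.", k, proc, bp
          ))
        }
      }
    }

    # assemble abstracts: 1-3 sentences each, planted first then noise
    all_sents <- c(vapply(sentences, `[[`, character(1), "text"), noise_sents)
    abstracts <- list()
    i <- 1L
    while (i <= length(all_sents)) {
      take <- min(sample.int(3L, 1), length(all_sents) - i + 1L)
      abstracts[[length(abstracts) + 1L]] <- tibble::tibble(
        pmid = sprintf("1%07d", length(abstracts) + 1L),
        title = sprintf("Synthetic abstract %d", length(abstracts) + 1L),
        abstract = paste(all_sents[i:(i + take - 1L)], collapse = " ")
      )
      i <- i + take
    }
    abstracts <- if (length(abstracts) > 0) dplyr::bind_rows(abstracts) else {
      tibble::tibble(pmid = character(), title = character(), abstract = character())
    }

    # parse graphs for every template-shaped sentence (the toy linker
    # cannot parse the plain distractors, mirroring real parser failures)
    parseable <- c(
      vapply(sentences, `[[`, character(1), "text"),
      noise_sents[grepl("induces", noise_sents)]
    )
    graphs <- purrr::imap(unique(parseable), function(s, k) {
      toy_linker(s, sentence_id = sprintf("sent%04d", k))
    })

    lexicon <- semantic_lexicon(
      term = c(subs$name, sim_processes, sim_diseases, sim_bodyparts),
      group = c(rep("SUBSTANCE", nrow(subs)),
                rep("PROCESS", length(sim_processes)),
                rep("DISEASE", length(sim_diseases)),
                rep("BODYPART", length(sim_bodyparts))),
      semantic_type = c(subs$semantic_type,
                        rep("Biologic Function", length(sim_processes)),
                        rep("Disease or Syndrome", length(sim_diseases)),
                        rep("Cell or Tissue", length(sim_bodyparts)))
    )
    chem <- chemical_records(subs$name, subs$semantic_type, subs$smiles,
                             subs$formula, subs$xlogp)

    paths <- list(
      xml = file.path(dir, "corpus.xml"),
      parses = file.path(dir, "parses.pg"),
      tagged = file.path(dir, "tagged.pg"),
      lexicon = file.path(dir, "lexicon.tsv"),
      chem = file.path(dir, "chem.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_medline_xml(abstracts, paths$xml)
    write_parse_file(graphs, paths$parses)
    write_parse_file(tagged_blocks, paths$tagged)
    write_semantic_lexicon(lexicon, paths$lexicon)
    write_chemical_records(chem, paths$chem)
    readr::write_tsv(
      dplyr::mutate(truth, dplyr::across(dplyr::everything(), \(x) dplyr::coalesce(x, "N/A"))),
      paths$truth, progress = FALSE
    )

    structure(
      list(
        paths = paths, truth = truth, chem = chem, lexicon = lexicon,
        abstracts = abstracts, tagged = tagged_blocks, seed = seed,
        n_relations = n_relations, noise_rate = noise_rate,
        similar_fraction = similar_fraction
      ),
      class = "planted_corpus"
    )
  })
}

#' @export
print.planted_corpus <- function(x, ...) {
  cat(sprintf(
    "<planted_corpus> seed %d: %d planted relations, noise rate %.2f, %d abstracts\n",
    x$seed, x$n_relations, x$noise_rate, nrow(x$abstracts)
  ))
  invisible(x)
}

#' Learn a rulebook from a planted corpus' training blocks
#'
#' @param corpus a `planted_corpus`.
#' @return list of [extraction_rule()] objects.
#' @export
corpus_rulebook <- function(corpus) {
  stopifnot(inherits(corpus, "planted_corpus"))
  purrr::list_flatten(purrr::map(corpus$tagged, learn_rules))
}

#' Precision and recall of extracted relations against planted truth
#'
#' Relations are compared on the five SEPDB fields (case- and
#' whitespace-normalized; absent and `"N/A"` are equivalent). True
#' positives are extracted relations present in the truth set; false
#' positives the rest; false negatives the truth relations never
#' extracted. An undefined ratio (empty denominator) is reported as 0 with
#' its `*_defined` flag set to `FALSE`.
#'
#' @param extracted relations tibble.
#' @param truth relations tibble (provenance columns ignored).
#' @return one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `precision_defined`, `recall_defined`.
#' @export
evaluate_extraction <- function(extracted, truth) {
  ek <- unique(relation_key(extracted))
  tk <- unique(relation_key(truth))
  tp <- length(intersect(ek, tk))
  fp <- length(setdiff(ek, tk))
  fn <- length(setdiff(tk, ek))
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else 0,
    recall = if (tp + fn > 0) tp / (tp + fn) else 0,
    precision_defined = tp + fp > 0,
    recall_defined = tp + fn > 0
  )
}
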