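test_that("corpus generation is byte-identical per seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  pc1 <- generate_corpus(seed = 42, n_relations = 12, noise_rate = 0.25, dir = d1)
  pc2 <- generate_corpus(seed = 42, n_relations = 12, noise_rate = 0.25, dir = d2)
  for (nm in names(pc1$paths)) {
    expect_identical(readLines(pc1$paths[[nm]]), readLines(pc2$paths[[nm]]),
                     info = nm)
  }
  # a different seed changes the corpus
  d3 <- withr::local_tempdir()
  pc3 <- generate_corpus(seed = 43, n_relations = 12, noise_rate = 0.25, dir = d3)
  expect_false(identical(readLines(pc1$paths$xml), readLines(pc3$paths$xml)))
})

test_that("an empty corpus yields no sentences and no relations", {
  pc <- generate_corpus(seed = 7, n_relations = 0, noise_rate = 0)
  expect_equal(nrow(pc$truth), 0)
  expect_equal(nrow(read_medline_xml(pc$paths$xml)), 0)
})

test_that("noise-free planted corpora are recovered perfectly", {
  pc <- generate_corpus(seed = 7, n_relations = 20, noise_rate = 0)
  rel <- run_extraction(pc$paths$xml, pc$paths$parses, corpus_rulebook(pc),
                        pc$lexicon)
  ev <- evaluate_extraction(rel, pc$truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$fp, 0)
  expect_equal(ev$fn, 0)
})

test_that("rules learned from training blocks re-extract their own sentences", {
  pc <- generate_corpus(seed = 3, n_relations = 8, noise_rate = 0)
  for (ts in pc$tagged) {
    rules <- learn_rules(ts)
    g <- ts$graph
    stem <- g$tokens$stem[ts$effect_index + 1]
    raw <- apply_rulebook(
      g, list(pmid = "p", sentence = "s", effect_surface = NA, effect_stem = stem),
      rules
    )
    tagged_texts <- vapply(seq_len(nrow(ts$tags)), function(i) {
      paste(g$tokens$surface[(ts$tags$start[i] + 1):(ts$tags$end[i] + 1)],
            collapse = " ")
    }, character(1))
    expect_setequal(unlist(raw$slots), tagged_texts)
  }
})

test_that("evaluation computes the precision/recall formulas", {
  t5 <- tibble::tibble(
    substance = paste0("s", 1:5), effect_type = "Increase",
    process = "p", disease = NA_character_, body_part = NA_character_
  )
  # perfect extraction
  ev <- evaluate_extraction(t5, t5)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  # nothing extracted: recall 0, precision undefined -> 0 with flag
  ev0 <- evaluate_extraction(t5[0, ], t5)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 0)
  expect_false(ev0$precision_defined)
  # TP=3, FP=1, FN=2: precision 0.75, recall 0.6
  extracted <- dplyr::bind_rows(
    t5[1:3, ],
    tibble::tibble(substance = "bogus", effect_type = "Increase",
                   process = "p", disease = NA_character_, body_part = NA_character_)
  )
  ev2 <- evaluate_extraction(extracted, t5)
  expect_equal(ev2$tp, 3)
  expect_equal(ev2$fp, 1)
  expect_equal(ev2$fn, 2)
  expect_equal(ev2$precision, 0.75)
  expect_equal(ev2$recall, 0.6)
  # matching is rendering-insensitive: "N/A" equals absent
  extr_na <- dplyr::mutate(t5, disease = "N/A", body_part = "N/A")
  expect_equal(evaluate_extraction(extr_na, t5)$precision, 1)
})

test_that("noise never increases recall and never breaks precision", {
  for (seed in c(5, 17)) {
    recalls <- vapply(c(0, 0.4, 0.8), function(nr) {
      pc <- generate_corpus(seed = seed, n_relations = 16, noise_rate = nr)
      rel <- run_extraction(pc$paths$xml, pc$paths$parses, corpus_rulebook(pc),
                            pc$lexicon)
      ev <- evaluate_extraction(rel, pc$truth)
      expect_equal(ev$precision, 1)  # distractors are rejected, not mis-extracted
      ev$recall
    }, numeric(1))
    expect_true(all(diff(recalls) <= 0))
  }
})

test_that("a planted similar pair yields exactly the predicted recombinations", {
  # two substances engineered similar, same effect type, different contexts
  chem <- chemical_records(
    name = c("Veratine", "Dolozole"),
    semantic_type = "Organic Chemical",
    smiles = c("CCc1ccccc1", "CCc1ccccc1C"),
    formula = c("C8H10", "C9H12"),
    xlogp = c(2.1, 2.3)
  )
  rel <- tibble::tibble(
    substance = c("Veratine", "Dolozole"),
    effect_type = "Increase",
    process = "apoptosis",
    disease = NA_character_,
    body_part = c("hepatocytes", "tumor cells")
  )
  hyp <- generate_hypotheses(rel, chem)
  expect_equal(nrow(hyp), 2)
  expect_setequal(hyp$substance, c("Veratine", "Dolozole"))
  expect_equal(hyp$body_part[hyp$substance == "Veratine"], "tumor cells")
  expect_equal(hyp$body_part[hyp$substance == "Dolozole"], "hepatocytes")
  # engineered pair: identical type, substructure MCS, close formula and XLogP
  s <- similarity_score(chem[1, ], chem[2, ])
  expect_gte(s$total, 2)
})

test_that("the full pipeline wrapper chains extraction and hypotheses", {
  pc <- generate_corpus(seed = 9, n_relations = 12, noise_rate = 0)
  rb <- corpus_rulebook(pc)
  out <- run_pipeline(pc$paths$xml, pc$paths$parses, rb, pc$paths$lexicon,
                      pc$paths$chem)
  expect_true(all(c("relations", "hypotheses") %in% names(out)))
  expect_equal(evaluate_extraction(out$relations, pc$truth)$recall, 1)
  if (nrow(out$hypotheses) > 0) {
    expect_true(all(out$hypotheses$score >= 2))
  }
})
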