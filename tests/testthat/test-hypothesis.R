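test_that("candidate pairing applies distinctness, effect type and threshold", {
  rel <- wogonin_fisetin_relations()
  chem <- wogonin_fisetin_chem()
  pairs <- candidate_pairs(rel, chem, structural = wogonin_fisetin_structural())
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$score, 4)
  expect_setequal(c(pairs$substance_a, pairs$substance_b), c("Wogonin", "Fisetin"))

  # two relations sharing a substance never pair
  rel_same <- rel
  rel_same$substance <- c("Wogonin", "wogonin")
  expect_equal(nrow(candidate_pairs(rel_same, chem,
                                    structural = wogonin_fisetin_structural())), 0)

  # opposite effect types never pair
  rel_eff <- rel
  rel_eff$effect_type <- c("Increase", "Reduction")
  expect_equal(nrow(candidate_pairs(rel_eff, chem,
                                    structural = wogonin_fisetin_structural())), 0)

  # a below-threshold pair is excluded (only semantic type matches: total 1)
  chem_far <- chem
  chem_far$formula <- c("C16H12O5", "C50H80N10")
  chem_far$xlogp <- c(2.74, 9)
  expect_equal(nrow(candidate_pairs(
    rel, chem_far,
    structural = dplyr::mutate(wogonin_fisetin_structural(), t = 0.1)
  )), 0)

  # a missing chemical record skips the pair with a warning
  expect_warning(
    p <- candidate_pairs(rel, chem[1, ], structural = wogonin_fisetin_structural()),
    class = "upk_missing_chem"
  )
  expect_equal(nrow(p), 0)
})

test_that("recombination swaps full contexts and produces the printed pair", {
  rel <- wogonin_fisetin_relations()
  pairs <- candidate_pairs(rel, wogonin_fisetin_chem(),
                           structural = wogonin_fisetin_structural())
  hyp <- rank_hypotheses(recombine(pairs, rel))
  expect_equal(nrow(hyp), 2)
  wog <- hyp[hyp$substance == "Wogonin", ]
  expect_equal(wog$process, "Apoptosis")
  expect_true(is.na(wog$disease))
  expect_equal(wog$body_part, "HCT-116 Cells")
  expect_equal(wog$score, 4)
  fis <- hyp[hyp$substance == "Fisetin", ]
  expect_equal(fis$body_part, "Malignant T Cells")
  expect_equal(fis$score, 4)
})

test_that("recombination drops duplicates of parents and extracted relations", {
  # identical context triples: both candidates replicate their parents
  rel <- wogonin_fisetin_relations()
  rel$body_part <- c("HCT-116 Cells", "HCT-116 Cells")
  pairs <- candidate_pairs(rel, wogonin_fisetin_chem(),
                           structural = wogonin_fisetin_structural())
  expect_equal(nrow(recombine(pairs, rel)), 0)

  # different processes transfer with the partner's full context
  rel2 <- wogonin_fisetin_relations()
  rel2$process <- c("Apoptosis", "mRNA expression of IL-1")
  rel2$body_part <- c("Malignant T Cells", NA)
  pairs2 <- candidate_pairs(rel2, wogonin_fisetin_chem(),
                            structural = wogonin_fisetin_structural())
  hyp2 <- recombine(pairs2, rel2)
  wog <- hyp2[hyp2$substance == "Wogonin", ]
  expect_equal(wog$process, "mRNA expression of IL-1")  # partner's process
  expect_true(is.na(wog$body_part))
})

test_that("ranking is score-descending with deterministic tie-breaks", {
  hyp <- tibble::tibble(
    substance = c("Zeta", "Alpha", "Mid", "Top"),
    effect_type = "Increase",
    process = c("p", "p", "p", "p"),
    disease = NA_character_,
    body_part = c("b", "b", "b", "b"),
    score = c(2, 2, 3.5, 4),
    partner_substance = "x", sources = "r1+r2"
  )
  r <- rank_hypotheses(hyp)
  expect_equal(r$score, c(4, 3.5, 2, 2))
  expect_equal(r$substance[3:4], c("Alpha", "Zeta"))  # lexicographic tie-break
  # permutation invariance
  for (perm in list(c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    expect_equal(rank_hypotheses(hyp[perm, ]), r)
  }
  # empty in, empty out
  expect_equal(nrow(rank_hypotheses(hyp[0, ])), 0)
})

test_that("every hypothesis respects threshold, cap and novelty", {
  pc <- generate_corpus(seed = 11, n_relations = 30, noise_rate = 0)
  rel <- run_extraction(pc$paths$xml, pc$paths$parses, corpus_rulebook(pc), pc$lexicon)
  pairs <- candidate_pairs(rel, pc$chem)
  hyp <- generate_hypotheses(rel, pc$chem)
  expect_true(all(hyp$score >= 2))
  expect_true(all(hyp$score <= 4))
  expect_lte(nrow(hyp), 2 * nrow(pairs))
  # novelty: no generated tuple equals an extracted one
  hyp_keys <- paste(tolower(hyp$substance), tolower(hyp$effect_type),
                    tolower(dplyr::coalesce(hyp$process, "n/a")),
                    tolower(dplyr::coalesce(hyp$disease, "n/a")),
                    tolower(dplyr::coalesce(hyp$body_part, "n/a")))
  rel_keys <- paste(tolower(rel$substance), tolower(rel$effect_type),
                    tolower(dplyr::coalesce(rel$process, "n/a")),
                    tolower(dplyr::coalesce(rel$disease, "n/a")),
                    tolower(dplyr::coalesce(rel$body_part, "n/a")))
  expect_length(intersect(hyp_keys, rel_keys), 0)
})

test_that("hypotheses TSV output renders N/A and keeps the score column", {
  rel <- wogonin_fisetin_relations()
  hyp <- generate_hypotheses(rel, wogonin_fisetin_chem(),
                             structural = wogonin_fisetin_structural())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hypotheses(hyp, f)
  lines <- readLines(f)
  expect_match(lines[1], "substance\teffect_type\tprocess\tdisease\tbody_part\tscore")
  expect_match(lines[2], "\tN/A\t")
  p <- plot_hypotheses(hyp)
  expect_s3_class(p, "ggplot")
})
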