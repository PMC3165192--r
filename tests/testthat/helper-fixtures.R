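# Worked-scenario fixtures: the Wogonin/Fisetin apoptosis pair and the
# Cordycepin/Fludarabine record attributes, as printed in the source
# tables a curator would transcribe.

wogonin_fisetin_relations <- function() {
  tibble::tibble(
    substance = c("Wogonin", "Fisetin"),
    effect_type = c("Increase", "Increase"),
    process = c("Apoptosis", "Apoptosis"),
    disease = c(NA_character_, NA_character_),
    body_part = c("Malignant T Cells", "HCT-116 Cells")
  )
}

wogonin_fisetin_chem <- function() {
  chemical_records(
    name = c("Wogonin", "Fisetin"),
    semantic_type = c("Organic Chemical", "Organic Chemical"),
    smiles = NA,
    formula = c("C_16_H_12_O_5_", "C_15_H_10_O_6_"),
    xlogp = c(2.74, 2.77)
  )
}

# printed structural similarity for the pair (reference-tool output)
wogonin_fisetin_structural <- function() {
  tibble::tibble(name_a = "Wogonin", name_b = "Fisetin", t = 0.75)
}

cordycepin_fludarabine_chem <- function() {
  chemical_records(
    name = c("Cordycepin", "Fludarabine"),
    semantic_type = c("Pharmacologic Substance", "Pharmacologic Substance"),
    smiles = NA,
    formula = c("C_10_H_13_N_5_O_3_", "C_10_H_12_FN_5_O_4_"),
    xlogp = c(-1.25, -1.38)
  )
}

# semantic lexicon covering the fixture sentences
fixture_lexicon <- function() {
  semantic_lexicon(
    term = c("fisetin", "wogonin", "docetaxel", "tolfenamic acid", "genistein",
             "apoptosis", "Sp protein degradation", "oxidative stress",
             "leukemia", "melanoma",
             "HCT-116 cells", "malignant T cells", "cancer cell lines",
             "tumor cells"),
    group = c(rep("SUBSTANCE", 5), rep("PROCESS", 3), rep("DISEASE", 2),
              rep("BODYPART", 4)),
    semantic_type = c("Organic Chemical", "Organic Chemical",
                      "Pharmacologic Substance", "Organic Chemical",
                      "Organic Chemical",
                      rep("Biologic Function", 3),
                      rep("Disease or Syndrome", 2),
                      rep("Cell or Tissue", 4))
  )
}

# convenience: graph + learned rules for an "X induces Y in Z" sentence
fixture_svo_pp <- function(sentence = "Fisetin induces apoptosis in HCT-116 cells") {
  g <- toy_linker(sentence)
  n <- nrow(g$tokens)
  ts <- tagged_sentence(
    g, 1L,
    tibble::tibble(
      start = c(0L, 2L, 4L), end = c(0L, 2L, n - 1L),
      placeholder = c("@SUBSTANCE", "@SYMPTOM", "@BODYPART")
    )
  )
  list(graph = g, tagged = ts, rules = learn_rules(ts))
}

rewrap_relation <- function(rel_row) {
  slots <- list()
  if (!is.na(rel_row$substance)) slots[["@SUBSTANCE"]] <- rel_row$substance
  if (!is.na(rel_row$process)) slots[["@SYMPTOM"]] <- rel_row$process
  if (!is.na(rel_row$disease)) slots[["@DISEASE"]] <- rel_row$disease
  if (!is.na(rel_row$body_part)) slots[["@BODYPART"]] <- rel_row$body_part
  structure(
    list(pmid = rel_row$pmid, sentence = rel_row$sentence,
         effect_surface = NA_character_,
         effect_stem = switch(rel_row$effect_type, Increase = "induc", Reduction = "reduc"),
         slots = slots),
    class = "raw_extraction"
  )
}
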