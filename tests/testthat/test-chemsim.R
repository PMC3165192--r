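test_that("molecular formulas parse exactly, with underscore variants", {
  f <- parse_formula("C10H13N5O3")
  expect_equal(f[["C"]], 10L)
  expect_equal(f[["H"]], 13L)
  expect_equal(f[["N"]], 5L)
  expect_equal(f[["O"]], 3L)
  expect_equal(sum(f), 31L)
  expect_equal(parse_formula("C_10_H_13_N_5_O_3_"), parse_formula("C10H13N5O3"))
  expect_equal(parse_formula("C")[["C"]], 1L)
  expect_equal(sum(parse_formula("C16H12O5")), 33L)
  expect_equal(parse_formula("C10H12FN5O4")[["F"]], 1L)
  expect_error(parse_formula("C10Qx3"), "unknown element")
  expect_error(parse_formula("10C"), "unexpected character")
})

test_that("atomic-count comparison follows relative Manhattan distance", {
  # printed pairs: d = 3/32 and 4/33, both under the 0.2 threshold
  expect_equal(atomic_comparative("C10H13N5O3", "C10H12FN5O4"), 1)
  expect_equal(atomic_comparative("C16H12O5", "C15H10O6"), 1)
  # very different sizes: d = 27/31
  expect_equal(atomic_comparative("CH4", "C10H13N5O3"), 0)
  # symmetric
  expect_equal(atomic_comparative("C10H12FN5O4", "C10H13N5O3"), 1)
})

test_that("the SMILES subset parses chains, rings, branches and brackets", {
  g <- parse_smiles("CCO")
  expect_equal(g$atoms$element, c("C", "C", "O"))
  expect_equal(nrow(g$bonds), 2)
  expect_false(any(g$atoms$aromatic))

  benzene <- parse_smiles("c1ccccc1")
  expect_equal(benzene$atoms$element, rep("C", 6))
  expect_true(all(benzene$atoms$aromatic))
  expect_equal(nrow(benzene$bonds), 6)

  asp <- parse_smiles("CC(N)C(=O)O")   # branches and a double bond
  expect_equal(n_atoms(asp), 6)
  expect_equal(nrow(asp$bonds), 5)

  brk <- parse_smiles("C[N+](C)(C)C")  # bracket atom with charge
  expect_equal(sort(brk$atoms$element), c("C", "C", "C", "C", "N"))

  noh <- parse_smiles("[H]OC([H])([H])[H]")  # explicit hydrogens dropped
  expect_equal(sort(noh$atoms$element), c("C", "O"))
  expect_equal(nrow(noh$bonds), 1)

  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(CC"), "unmatched")
  expect_error(parse_smiles("C$C"), "position 2")
})

test_that("MCS equals the exhaustive oracle on all fixture molecule pairs", {
  mols <- fixture_molecules()
  for (i in seq_along(mols)) {
    for (j in i:length(mols)) {
      m <- mcs_size(mols[[i]], mols[[j]])
      expect_false(attr(m, "lower_bound"))
      expect_equal(
        as.integer(m), oracle_mcs_size(mols[[i]], mols[[j]]),
        info = paste(names(mols)[i], "vs", names(mols)[j])
      )
    }
  }
})

test_that("MCS special cases: identity, chain extension, no common atom", {
  benzene <- parse_smiles("c1ccccc1")
  expect_equal(as.integer(mcs_size(benzene, benzene)), 6L)
  expect_equal(as.integer(mcs_size(parse_smiles("CCO"), parse_smiles("CCCO"))), 3L)
  expect_equal(as.integer(mcs_size(parse_smiles("C"), parse_smiles("N"))), 0L)
  # aromatic flag must agree: benzene shares no atom with cyclohexane
  expect_equal(as.integer(mcs_size(benzene, parse_smiles("C1CCCCC1"))), 0L)
})

test_that("MCS-Tanimoto values and substructure flags are exact", {
  tm_id <- tanimoto_mcs(parse_smiles("CCO"), parse_smiles("CCO"))
  expect_equal(tm_id$t, 1)
  expect_true(tm_id$substructure)

  tm <- tanimoto_mcs(parse_smiles("CCO"), parse_smiles("CCCO"))
  expect_equal(tm$t, 0.75)
  expect_true(tm$substructure)

  tm2 <- tanimoto_mcs(parse_smiles("c1ccccc1"), parse_smiles("c1ccncc1"))
  expect_equal(tm2$t, 5 / 7)
  expect_false(tm2$substructure)

  # t = 1 exactly when the graphs match entirely under the matching rules
  mols <- fixture_molecules()
  for (i in seq_along(mols)) {
    for (j in seq_along(mols)) {
      tm <- tanimoto_mcs(mols[[i]], mols[[j]])
      expect_gte(tm$t, 0)
      expect_lte(tm$t, 1)
      if (i == j) expect_equal(tm$t, 1)
    }
  }
})

test_that("comparative bands map printed component values correctly", {
  # structural: 0.9 and 0.75 are Similar; substructure earns the mid band
  expect_equal(structural_comparative(0.9), 1)
  expect_equal(structural_comparative(0.75), 1)
  expect_equal(structural_comparative(0.4, substructure = TRUE), 0.5)
  expect_equal(structural_comparative(0.4, substructure = FALSE), 0)

  # XLogP bands, including both printed pairs and the boundary reading
  expect_equal(xlogp_comparative(-1.25, -1.38), 1)
  expect_equal(xlogp_comparative(2.74, 2.77), 1)
  expect_equal(xlogp_comparative(0.0, 0.7), 0.5)
  expect_equal(xlogp_comparative(0.0, 0.5), 1)   # boundary: exactly 0.5 apart
  expect_equal(xlogp_comparative(0.0, 1.0), 0)   # boundary: exactly 1 apart

  # semantic type: case-folded equality; missing types never match
  expect_equal(semtype_comparative("Pharmacologic Substance", "Pharmacologic Substance"), 1)
  expect_equal(semtype_comparative("Organic Chemical", "Pharmacologic Substance"), 0)
  expect_equal(semtype_comparative("", "Organic Chemical"), 0)
})

test_that("the printed worked scenarios both total 4", {
  cf <- cordycepin_fludarabine_chem()
  s1 <- similarity_score(cf[1, ], cf[2, ], structural_similarity = 0.9)
  expect_equal(unname(s1$components), c(1, 1, 1, 1))
  expect_equal(s1$total, 4)

  wf <- wogonin_fisetin_chem()
  s2 <- similarity_score(wf[1, ], wf[2, ], structural_similarity = 0.75)
  expect_equal(s2$total, 4)
})

test_that("similarity is symmetric, maximal at identity and half-point quantized", {
  recs <- chemical_records(
    name = c("ethanol", "propanol", "benzene", "alanine"),
    semantic_type = c("Organic Chemical", "Organic Chemical",
                      "Organic Chemical", "Amino Acid"),
    smiles = c("CCO", "CCCO", "c1ccccc1", "CC(N)C(=O)O"),
    formula = c("C2H6O", "C3H8O", "C6H6", "C3H7NO2"),
    xlogp = c(-0.1, 0.3, 2.1, -3.0)
  )
  for (i in seq_len(nrow(recs))) {
    expect_equal(similarity_score(recs[i, ], recs[i, ])$total, 4)
    for (j in seq_len(nrow(recs))) {
      sij <- similarity_score(recs[i, ], recs[j, ])
      sji <- similarity_score(recs[j, ], recs[i, ])
      expect_equal(sij$components, sji$components)
      expect_true(sij$total %in% seq(0, 4, by = 0.5))
      expect_lte(sij$total, 4)
    }
  }
  # two records differing in every component beyond all thresholds
  far <- similarity_score(recs[3, ], recs[4, ])
  expect_equal(far$total, 0)
})

test_that("missing record fields degrade the component to 0 with a warning", {
  a <- chemical_records("a", "T1", NA, NA, NA)
  b <- chemical_records("b", "T1", "CCO", "C2H6O", 1)
  warns <- character(0)
  withCallingHandlers(
    s <- similarity_score(a, b),
    upk_degraded = function(c) {
      warns <<- c(warns, conditionMessage(c))
      invokeRestart("muffleWarning")
    }
  )
  expect_length(warns, 3)  # structural, atomic and XLogP all degraded
  expect_equal(s$components[["semtype"]], 1)
  expect_equal(s$components[["structural"]], 0)
  expect_equal(s$components[["atomic"]], 0)
  expect_equal(s$components[["xlogp"]], 0)
})

test_that("tidy and glance expose the breakdown as tibbles", {
  wf <- wogonin_fisetin_chem()
  s <- similarity_score(wf[1, ], wf[2, ], structural_similarity = 0.75)
  td <- tidy(s)
  expect_equal(td$component, c("semtype", "structural", "atomic", "xlogp"))
  expect_equal(sum(td$comparative), 4)
  gl <- glance(s)
  expect_equal(gl$total, 4)
  expect_equal(gl$name_a, "Wogonin")
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
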