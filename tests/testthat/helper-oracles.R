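# Exhaustive oracle for the connected maximum common subgraph: enumerates
# every connected common mapping by growing one common-bond-attached pair at
# a time, deduplicating mapping sets. Independent of the package's
# backtracking search; only feasible for small molecules.
oracle_mcs_size <- function(a, b) {
  la <- paste0(a$atoms$element, ifelse(a$atoms$aromatic, ":ar", ""))
  lb <- paste0(b$atoms$element, ifelse(b$atoms$aromatic, ":ar", ""))
  na <- length(la)
  nb <- length(lb)
  Aa <- matrix(FALSE, na, na)
  for (r in seq_len(nrow(a$bonds))) {
    Aa[a$bonds[r, 1], a$bonds[r, 2]] <- TRUE
    Aa[a$bonds[r, 2], a$bonds[r, 1]] <- TRUE
  }
  Ab <- matrix(FALSE, nb, nb)
  for (r in seq_len(nrow(b$bonds))) {
    Ab[b$bonds[r, 1], b$bonds[r, 2]] <- TRUE
    Ab[b$bonds[r, 2], b$bonds[r, 1]] <- TRUE
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  best <- 0L
  grow <- function(pa, pb) {
    key <- paste(sort(paste0(pa, ".", pb)), collapse = ";")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    if (length(pa) > best) best <<- length(pa)
    for (v in setdiff(seq_len(na), pa)) {
      for (w in setdiff(seq_len(nb), pb)) {
        if (la[v] != lb[w]) next
        # must attach through a bond common to both molecules
        attached <- any(Aa[v, pa] & Ab[w, pb])
        if (attached) grow(c(pa, v), c(pb, w))
      }
    }
    invisible()
  }
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (la[i] == lb[j]) grow(i, j)
    }
  }
  best
}

# small-molecule fixture set (all <= 12 heavy atoms)
fixture_smiles <- c(
  ethanol      = "CCO",
  propanol     = "CCCO",
  acetic_acid  = "CC(=O)O",
  benzene      = "c1ccccc1",
  pyridine     = "c1ccncc1",
  cyclohexane  = "C1CCCCC1",
  thf          = "C1CCOC1",
  alanine      = "CC(N)C(=O)O",
  cresol       = "Cc1ccccc1O",
  chloroform   = "ClC(Cl)Cl",
  triethylamine = "CCN(CC)CC"
)

fixture_molecules <- function() lapply(fixture_smiles, parse_smiles)
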