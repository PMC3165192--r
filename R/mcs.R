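# Connected maximum common subgraph between two heavy-atom graphs.
#
# The search is a McGregor-style backtracking extension: a partial atom
# mapping grows only through pairs that share a common bond with an already
# mapped pair, so the common subgraph is connected by construction. Atom
# compatibility requires equal element and equal aromatic flag; bond orders
# play no role. Expansion order is deterministic (ascending atom indices),
# and a step budget caps the search on large inputs, in which case the
# result is flagged as a lower bound.

mcs_adjacency <- function(graph) {
  n <- n_atoms(graph)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  b <- graph$bonds
  for (r in seq_len(nrow(b))) {
    adj[[b[r, 1]]] <- c(adj[[b[r, 1]]], b[r, 2])
    adj[[b[r, 2]]] <- c(adj[[b[r, 2]]], b[r, 1])
  }
  lapply(adj, sort)
}

atom_labels <- function(graph) {
  paste0(graph$atoms$element, ifelse(graph$atoms$aromatic, ":ar", ""))
}

#' Size of a maximum common connected subgraph
#'
#' Returns the number of heavy atoms in the largest connected subgraph
#' common to both molecules under element + aromaticity atom matching
#' (bond orders ignored). Exact within the step budget; if the budget is
#' exhausted the best size found so far is returned with attribute
#' `lower_bound = TRUE`.
#'
#' @param a,b [mol_graph()] objects, both non-empty.
#' @param max_steps search-node budget before the result is declared a
#'   lower bound.
#' @return integer MCS atom count; attribute `lower_bound` is `TRUE` when
#'   the search was capped.
#' @export
mcs_size <- function(a, b, max_steps = 2e6) {
  stopifnot(inherits(a, "mol_graph"), inherits(b, "mol_graph"))
  if (n_atoms(a) == 0 || n_atoms(b) == 0) rlang::abort("both molecules must be non-empty")
  # search from the smaller side
  if (n_atoms(a) > n_atoms(b)) {
    tmp <- a; a <- b; b <- tmp
  }
  na <- n_atoms(a)
  nb <- n_atoms(b)
  la <- atom_labels(a)
  lb <- atom_labels(b)
  adja <- mcs_adjacency(a)
  adjb <- mcs_adjacency(b)
  compat <- lapply(seq_len(na), function(i) which(lb == la[i]))
  if (all(lengths(compat) == 0)) {
    return(structure(0L, lower_bound = FALSE))
  }

  best <- 0L
  steps <- 0L
  capped <- FALSE
  mapa <- rep(NA_integer_, na)
  mapb <- rep(NA_integer_, nb)

  extend <- function(size) {
    steps <<- steps + 1L
    if (steps > max_steps) {
      capped <<- TRUE
      return(invisible())
    }
    if (size > best) best <<- size
    if (best == na) return(invisible())
    # candidate pairs adjacent (via a common bond) to the current mapping
    mapped_a <- which(!is.na(mapa))
    cand <- list()
    seen <- character(0)
    for (u in mapped_a) {
      bu <- mapa[u]
      for (v in adja[[u]]) {
        if (!is.na(mapa[v])) next
        for (w in adjb[[bu]]) {
          if (!is.na(mapb[w]) || lb[w] != la[v]) next
          key <- paste0(v, "_", w)
          if (!key %in% seen) {
            seen <- c(seen, key)
            cand[[length(cand) + 1L]] <- c(v, w)
          }
        }
      }
    }
    if (length(cand) == 0) return(invisible())
    # upper bound: even mapping every remaining unmapped a-atom cannot beat best
    if (size + (na - size) <= best) return(invisible())
    ord <- order(
      vapply(cand, `[`, integer(1), 1L),
      vapply(cand, `[`, integer(1), 2L)
    )
    for (k in ord) {
      v <- cand[[k]][1]
      w <- cand[[k]][2]
      if (capped) return(invisible())
      if (!is.na(mapa[v]) || !is.na(mapb[w])) next
      mapa[v] <<- w
      mapb[w] <<- v
      extend(size + 1L)
      mapa[v] <<- NA_integer_
      mapb[w] <<- NA_integer_
    }
    invisible()
  }

  # deterministic seeding: each compatible pair in ascending order
  for (i in seq_len(na)) {
    if (best == na || capped) break
    for (j in compat[[i]]) {
      if (best == na || capped) break
      mapa[i] <- j
      mapb[j] <- i
      extend(1L)
      mapa[i] <- NA_integer_
      mapb[j] <- NA_integer_
    }
  }
  structure(as.integer(best), lower_bound = capped)
}

#' MCS-Tanimoto structural similarity
#'
#' Computes `t = m / (|a| + |b| - m)` where `m` is the connected MCS atom
#' count — a similarity in `[0, 1]` equal to 1 exactly when the two graphs
#' match entirely. The substructure flag is true when the smaller molecule
#' maps completely into the larger one.
#'
#' @inheritParams mcs_size
#' @return list with `t` (similarity), `substructure` (flag), `mcs` (atom
#'   count) and `lower_bound` (search-cap flag).
#' @examples
#' tanimoto_mcs(parse_smiles("CCO"), parse_smiles("CCCO"))
#' @export
tanimoto_mcs <- function(a, b, max_steps = 2e6) {
  m <- mcs_size(a, b, max_steps = max_steps)
  t <- as.integer(m) / (n_atoms(a) + n_atoms(b) - as.integer(m))
  list(
    t = t,
    substructure = as.integer(m) == min(n_atoms(a), n_atoms(b)),
    mcs = as.integer(m),
    lower_bound = isTRUE(attr(m, "lower_bound"))
  )
}
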