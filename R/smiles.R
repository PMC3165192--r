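element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "Pt", "Au", "Hg", "Tl", "Pb", "Bi"
)

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style notation (`C10H13N5O3`) and the underscore-subscript
#' variant (`C_10_H_13_N_5_O_3_`). Repeated element symbols accumulate.
#'
#' @param formula a single formula string.
#' @return named integer vector of element counts, with attribute `total`
#'   (the total atom count, also available as `sum(...)`).
#' @examples
#' parse_formula("C10H13N5O3")
#' @export
parse_formula <- function(formula) {
  stopifnot(length(formula) == 1)
  s <- gsub("_", "", formula)
  if (s == "") rlang::abort("empty molecular formula")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    m <- stringr::str_match(substr(s, pos, n), "^([A-Z][a-z]?)([0-9]*)")
    sym <- m[1, 2]
    if (is.na(sym)) {
      rlang::abort(sprintf("formula '%s': unexpected character at position %d", formula, pos))
    }
    # prefer the two-letter symbol but fall back to one letter ("CO" = C + O)
    if (nchar(sym) == 2L && !sym %in% element_symbols) {
      sym <- substr(sym, 1L, 1L)
      m[1, 3] <- ""
    }
    if (!sym %in% element_symbols) {
      rlang::abort(sprintf("formula '%s': unknown element '%s'", formula, sym))
    }
    pos <- pos + nchar(sym)
    digits <- stringr::str_match(substr(s, pos, n), "^[0-9]+")[1, 1]
    cnt <- if (is.na(digits)) 1L else as.integer(digits)
    if (!is.na(digits)) pos <- pos + nchar(digits)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
  }
  structure(counts, total = sum(counts))
}

#' Construct a molecular graph
#'
#' Heavy atoms only: `atoms` records the element and an aromatic flag,
#' `bonds` the unordered atom-index pairs. This is the substrate of the
#' maximum-common-subgraph structural similarity.
#'
#' @param element character vector of element symbols.
#' @param aromatic logical vector of aromatic flags.
#' @param bonds two-column matrix/data frame of 1-based atom index pairs;
#'   may have zero rows.
#' @return an object of class `mol_graph` with fields `atoms` (tibble) and
#'   `bonds` (integer matrix with columns `i`, `j`, `i < j`).
#' @export
mol_graph <- function(element, aromatic = rep(FALSE, length(element)), bonds = NULL) {
  n <- length(element)
  if (is.null(bonds) || NROW(bonds) == 0) {
    bm <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  } else {
    bm <- as.matrix(bonds)[, 1:2, drop = FALSE]
    storage.mode(bm) <- "integer"
    bm <- cbind(i = pmin(bm[, 1], bm[, 2]), j = pmax(bm[, 1], bm[, 2]))
    if (any(bm[, 1] < 1L | bm[, 2] > n)) rlang::abort("bond refers to an invalid atom index")
    if (any(bm[, 1] == bm[, 2])) rlang::abort("self-bonds are not allowed")
    bm <- unique(bm)
  }
  structure(
    list(
      atoms = tibble::tibble(element = element, aromatic = as.logical(aromatic)),
      bonds = bm
    ),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d heavy atoms, %d bonds\n", nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param graph a [mol_graph()].
#' @return integer atom count.
#' @export
n_atoms <- function(graph) nrow(graph$atoms)

smiles_organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
smiles_aromatic_organic <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' Supports the subset needed for small-molecule similarity: organic-subset
#' atoms, bracket atoms (isotope, charge and H-counts accepted and
#' discarded), branches, ring-closure digits and `%nn` pairs, bond symbols
#' (`- = # : / \`, all recorded simply as bonds), aromatic lower-case
#' atoms, and `.` as a fragment separator. Explicit hydrogens (`[H]`) are
#' dropped: the result is a heavy-atom graph. Stereo marks (`@`) inside
#' brackets are ignored.
#'
#' @param smiles a single SMILES string.
#' @return a [mol_graph()].
#' @examples
#' parse_smiles("c1ccccc1")
#' @export
parse_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1)
  s <- smiles
  n <- nchar(s)
  if (n == 0) rlang::abort("empty SMILES string")
  perr <- function(pos, msg) {
    rlang::abort(sprintf("SMILES '%s': %s at position %d", smiles, msg, pos))
  }
  elements <- character(0)
  aromatic <- logical(0)
  hydrogens <- integer(0)  # indices of explicit [H] atoms, removed at the end
  bonds <- list()
  prev <- NA_integer_     # atom awaiting a bond to the next atom
  stack <- integer(0)     # branch return points
  ring <- list()          # open ring-closure labels -> atom index
  pos <- 1L

  new_atom <- function(elem, arom) {
    elements[length(elements) + 1L] <<- elem
    aromatic[length(aromatic) + 1L] <<- arom
    idx <- length(elements)
    if (!is.na(prev)) bonds[[length(bonds) + 1L]] <<- c(prev, idx)
    prev <<- idx
    idx
  }

  while (pos <= n) {
    ch <- substr(s, pos, pos)
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      # bond order/stereo is not recorded; symbol simply consumed
      pos <- pos + 1L
    } else if (ch == "(") {
      if (is.na(prev)) perr(pos, "branch with no preceding atom")
      stack <- c(stack, prev)
      pos <- pos + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) perr(pos, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pos <- pos + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        lab <- substr(s, pos + 1L, pos + 2L)
        if (!grepl("^[0-9]{2}$", lab)) perr(pos, "'%' needs two digits")
        pos <- pos + 3L
      } else {
        lab <- ch
        pos <- pos + 1L
      }
      if (is.na(prev)) perr(pos, "ring closure with no preceding atom")
      if (!is.null(ring[[lab]])) {
        bonds[[length(bonds) + 1L]] <- c(ring[[lab]], prev)
        ring[[lab]] <- NULL
      } else {
        ring[[lab]] <- prev
      }
    } else if (ch == "[") {
      close <- regexpr("]", substr(s, pos, n), fixed = TRUE)
      if (close < 0) perr(pos, "unmatched '['")
      body <- substr(s, pos + 1L, pos + close - 2L)
      bm <- stringr::str_match(body, "^([0-9]*)([A-Za-z][a-z]?)")
      sym <- bm[1, 3]
      if (is.na(sym)) perr(pos, "bracket atom with no element symbol")
      arom <- sym == tolower(sym) && sym %in% smiles_aromatic_organic
      elem <- if (arom) toupper(sym) else sym
      if (nchar(elem) == 2L && !elem %in% element_symbols) {
        elem <- substr(elem, 1L, 1L)
      }
      if (!elem %in% element_symbols) perr(pos, paste0("unknown element '", sym, "'"))
      if (elem == "H") {
        idx <- new_atom("H", FALSE)
        hydrogens <- c(hydrogens, idx)
      } else {
        new_atom(elem, arom)
      }
      pos <- pos + close
    } else if (grepl("^[A-Z]$", ch)) {
      two <- substr(s, pos, pos + 1L)
      if (two %in% c("Cl", "Br")) {
        new_atom(two, FALSE)
        pos <- pos + 2L
      } else if (ch %in% smiles_organic) {
        new_atom(ch, FALSE)
        pos <- pos + 1L
      } else {
        perr(pos, paste0("unsupported atom '", ch, "'"))
      }
    } else if (grepl("^[a-z]$", ch)) {
      if (!ch %in% smiles_aromatic_organic) perr(pos, paste0("unsupported aromatic atom '", ch, "'"))
      new_atom(toupper(ch), TRUE)
      pos <- pos + 1L
    } else {
      perr(pos, paste0("unexpected character '", ch, "'"))
    }
  }
  if (length(stack) > 0) perr(n, "unmatched '('")
  if (length(ring) > 0) {
    perr(n, paste0("unclosed ring bond(s): ", paste(names(ring), collapse = ", ")))
  }

  bm <- if (length(bonds) == 0) NULL else do.call(rbind, bonds)
  if (length(hydrogens) > 0) {
    keep <- setdiff(seq_along(elements), hydrogens)
    remap <- match(seq_along(elements), keep)
    if (!is.null(bm)) {
      bm <- bm[!(bm[, 1] %in% hydrogens | bm[, 2] %in% hydrogens), , drop = FALSE]
      bm[] <- remap[bm]
    }
    elements <- elements[keep]
    aromatic <- aromatic[keep]
  }
  if (length(elements) == 0) rlang::abort("SMILES contains no heavy atom")
  mol_graph(elements, aromatic, bm)
}
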