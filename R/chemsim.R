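#' Default pipeline configuration
#'
#' Thresholds and knobs for the similarity measure and the extraction
#' layer. Values are dimensionless unless noted.
#'
#' * `structural_threshold` (0.75): MCS-Tanimoto at or above which two
#'   structures count as Similar (comparative 1); below it, a substructure
#'   relationship still earns 0.5.
#' * `atomic_threshold` (0.2): relative Manhattan distance between element
#'   counts at or below which atomic counts count as Similar.
#' * `xlogp_similar` (0.5) / `xlogp_somewhat` (1): |XLogP| difference bands
#'   — at most 0.5 is Similar (1), strictly between 0.5 and 1 is Somewhat
#'   similar (0.5), 1 or more is Not similar (0).
#' * `score_threshold` (2): minimum pair similarity for hypothesis
#'   generation.
#' * `expansion_links` (`AN`, `A`, `G`): reduced link labels traversed when
#'   expanding entity names.
#' * `mcs_max_steps`: search budget for the MCS backtracking.
#'
#' @param ... named overrides of the defaults.
#' @return a named list.
#' @export
upk_config <- function(...) {
  cfg <- list(
    structural_threshold = 0.75,
    atomic_threshold = 0.2,
    xlogp_similar = 0.5,
    xlogp_somewhat = 1,
    score_threshold = 2,
    expansion_links = c("AN", "A", "G"),
    mcs_max_steps = 2e6
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  utils::modifyList(cfg, over)
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; `#` comments. `expansion_links` takes a
#' comma-separated list; numeric keys are coerced.
#'
#' @param path file path.
#' @return a config list as from [upk_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  kv <- stringr::str_match(lines, "^([A-Za-z_]+)\\s*=\\s*(.+)$")
  if (any(is.na(kv[, 1]))) {
    rlang::abort(sprintf("config line %d is not 'key = value'", which(is.na(kv[, 1]))[1]))
  }
  args <- list()
  for (i in seq_len(nrow(kv))) {
    key <- kv[i, 2]
    val <- stringr::str_trim(kv[i, 3])
    args[[key]] <- if (key == "expansion_links") {
      stringr::str_trim(stringr::str_split_1(val, ","))
    } else {
      as.numeric(val)
    }
  }
  do.call(upk_config, args)
}

#' Build a chemical-record tibble
#'
#' One row per substance: name, UMLS-style semantic type, SMILES, molecular
#' formula and XLogP. Stands in for the manual chemical-database lookups a
#' curator would do; any field other than the name may be `NA`, in which
#' case the corresponding similarity component degrades to 0 with a
#' warning.
#'
#' @param name,semantic_type,smiles,formula,xlogp vectors of equal length.
#' @return a tibble with those columns; names must be unique.
#' @export
chemical_records <- function(name, semantic_type = NA, smiles = NA,
                             formula = NA, xlogp = NA) {
  out <- tibble::tibble(
    name = as.character(name),
    semantic_type = as.character(semantic_type),
    smiles = as.character(smiles),
    formula = as.character(formula),
    xlogp = as.numeric(xlogp)
  )
  if (anyDuplicated(fold_term(out$name)) > 0) {
    rlang::abort("chemical record names must be unique (case-insensitively)")
  }
  out
}

#' Read a chemical-records TSV
#'
#' Format: `name<TAB>semantic_type<TAB>smiles<TAB>formula<TAB>xlogp`, with
#' header; `NA` or empty fields allowed.
#'
#' @param path file path.
#' @return a [chemical_records()] tibble.
#' @export
read_chemical_records <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#", progress = FALSE,
    col_types = readr::cols(
      name = readr::col_character(), semantic_type = readr::col_character(),
      smiles = readr::col_character(), formula = readr::col_character(),
      xlogp = readr::col_double()
    )
  )
  chemical_records(df$name, df$semantic_type, df$smiles, df$formula, df$xlogp)
}

#' Write a chemical-records TSV
#' @param records a [chemical_records()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chemical_records <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Semantic-type comparative value
#'
#' 1 when both type strings are non-empty and equal after case-folding,
#' else 0 — substances under the same ontology category are presumed to act
#' similarly.
#'
#' @param t1,t2 semantic type strings.
#' @return 0 or 1.
#' @export
semtype_comparative <- function(t1, t2) {
  if (is.na(t1) || is.na(t2) || t1 == "" || t2 == "") return(0)
  as.numeric(tolower(stringr::str_squish(t1)) == tolower(stringr::str_squish(t2)))
}

#' Atomic-count comparative value
#'
#' Compares element counts by relative Manhattan distance
#' `d = sum_e |a_e - b_e| / max(total_a, total_b)`; 1 (Similar) when
#' `d <= threshold`, else 0.
#'
#' @param a,b element-count vectors from [parse_formula()], or formula
#'   strings.
#' @param threshold relative distance cut-off (default 0.2).
#' @return 0 or 1.
#' @export
atomic_comparative <- function(a, b, threshold = 0.2) {
  if (is.character(a)) a <- parse_formula(a)
  if (is.character(b)) b <- parse_formula(b)
  elems <- union(names(a), names(b))
  av <- ifelse(elems %in% names(a), a[elems], 0L)
  bv <- ifelse(elems %in% names(b), b[elems], 0L)
  d <- sum(abs(av - bv)) / max(sum(a), sum(b))
  as.numeric(d <= threshold)
}

#' Structural comparative value
#'
#' Maps an MCS-Tanimoto similarity through the comparative-value bands:
#' 1 (Similar) at or above the threshold, 0.5 when one molecule is a
#' substructure of the other, 0 otherwise.
#'
#' @param t similarity in `[0, 1]`.
#' @param substructure logical substructure flag.
#' @param threshold Similar cut-off (default 0.75).
#' @return 0, 0.5 or 1.
#' @export
structural_comparative <- function(t, substructure = FALSE, threshold = 0.75) {
  stopifnot(t >= 0, t <= 1)
  if (t >= threshold) 1 else if (isTRUE(substructure)) 0.5 else 0
}

#' XLogP comparative value
#'
#' Bands on the absolute difference: at most `similar` apart is Similar
#' (1), strictly between `similar` and `somewhat` is Somewhat similar
#' (0.5), `somewhat` or more apart is Not similar (0).
#'
#' @param x1,x2 XLogP values.
#' @param similar,somewhat band edges (defaults 0.5 and 1).
#' @return 0, 0.5 or 1.
#' @export
xlogp_comparative <- function(x1, x2, similar = 0.5, somewhat = 1) {
  stopifnot(is.finite(x1), is.finite(x2))
  d <- abs(x1 - x2)
  if (d <= similar) 1 else if (d < somewhat) 0.5 else 0
}

#' Four-component similarity between two substances
#'
#' Sums the four comparative values — semantic type, structural
#' (MCS-Tanimoto), atomic count and XLogP — each contributing 0, 0.5 or 1,
#' for a total in `[0, 4]`. The measure is symmetric, and a complete record
#' scored against itself attains the maximum 4. A missing field degrades
#' that component to 0 with a warning rather than failing.
#'
#' @param a,b one-row data frames with columns `name`, `semantic_type`,
#'   `smiles`, `formula`, `xlogp` (see [chemical_records()]).
#' @param structural_similarity optionally a precomputed structural
#'   similarity in `[0, 1]` (e.g. printed by a reference structure tool);
#'   when `NULL` it is computed from the SMILES fields.
#' @param substructure substructure flag accompanying a supplied
#'   `structural_similarity`.
#' @param config a [upk_config()] list.
#' @return an object of class `upk_similarity`: fields `name_a`, `name_b`,
#'   `components` (named vector: semtype, structural, atomic, xlogp),
#'   `total`, and `structural_detail`. Supports [tidy()][generics::tidy]
#'   and [glance()][generics::glance].
#' @examples
#' a <- chemical_records("ethanol", "Organic Chemical", "CCO", "C2H6O", -0.1)
#' b <- chemical_records("propanol", "Organic Chemical", "CCCO", "C3H8O", 0.3)
#' similarity_score(a, b)
#' @export
similarity_score <- function(a, b, structural_similarity = NULL,
                             substructure = FALSE, config = upk_config()) {
  a <- as.list(a[1, ])
  b <- as.list(b[1, ])
  degrade <- function(component) {
    rlang::warn(sprintf("%s unavailable for '%s' / '%s'; component scored 0",
                        component, a$name, b$name),
                class = "upk_degraded")
    0
  }

  semtype <- semtype_comparative(a$semantic_type %||% NA, b$semantic_type %||% NA)

  detail <- list(t = NA_real_, substructure = NA, lower_bound = FALSE)
  structural <- if (!is.null(structural_similarity)) {
    detail$t <- structural_similarity
    detail$substructure <- substructure
    structural_comparative(structural_similarity, substructure,
                           threshold = config$structural_threshold)
  } else if (!is.null(a$smiles) && !is.null(b$smiles) &&
             !is.na(a$smiles) && !is.na(b$smiles)) {
    tm <- tanimoto_mcs(parse_smiles(a$smiles), parse_smiles(b$smiles),
                       max_steps = config$mcs_max_steps)
    detail <- tm
    structural_comparative(tm$t, tm$substructure, threshold = config$structural_threshold)
  } else {
    degrade("structural similarity")
  }

  atomic <- if (!is.null(a$formula) && !is.null(b$formula) &&
                !is.na(a$formula) && !is.na(b$formula)) {
    atomic_comparative(a$formula, b$formula, threshold = config$atomic_threshold)
  } else {
    degrade("atomic count")
  }

  xlogp <- if (!is.null(a$xlogp) && !is.null(b$xlogp) &&
               is.finite(a$xlogp %||% NA) && is.finite(b$xlogp %||% NA)) {
    xlogp_comparative(a$xlogp, b$xlogp,
                      similar = config$xlogp_similar, somewhat = config$xlogp_somewhat)
  } else {
    degrade("XLogP")
  }

  components <- c(semtype = semtype, structural = structural,
                  atomic = atomic, xlogp = xlogp)
  structure(
    list(
      name_a = a$name %||% NA_character_,
      name_b = b$name %||% NA_character_,
      components = components,
      total = sum(components),
      structural_detail = detail
    ),
    class = "upk_similarity"
  )
}

#' @export
print.upk_similarity <- function(x, ...) {
  cat(sprintf("<upk_similarity> %s vs %s\n", x$name_a, x$name_b))
  print(x$components)
  cat("total:", x$total, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a similarity breakdown into one row per component
#' @param x an `upk_similarity` object.
#' @param ... unused.
#' @return tibble with columns `component`, `comparative`.
#' @method tidy upk_similarity
#' @export
tidy.upk_similarity <- function(x, ...) {
  tibble::tibble(
    component = names(x$components),
    comparative = unname(x$components)
  )
}

#' One-row summary of a similarity breakdown
#' @param x an `upk_similarity` object.
#' @param ... unused.
#' @return tibble with `name_a`, `name_b`, the four components and `total`.
#' @method glance upk_similarity
#' @export
glance.upk_similarity <- function(x, ...) {
  tibble::tibble(
    name_a = x$name_a, name_b = x$name_b,
    semtype = x$components[["semtype"]],
    structural = x$components[["structural"]],
    atomic = x$components[["atomic"]],
    xlogp = x$components[["xlogp"]],
    total = x$total
  )
}

#' Bar chart of a similarity breakdown
#' @param object an `upk_similarity` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot upk_similarity
#' @export
autoplot.upk_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$comparative)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = sprintf("%s vs %s (total %.1f)", object$name_a, object$name_b, object$total),
      x = NULL, y = "comparative value"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
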