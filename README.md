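# upkminer

Literature-based discovery from biomedical abstracts: extract
substance–effect–process–disease–body-part (SEPDB) relations with learned
path rules over link-grammar-style parse graphs, score substance pairs
with a four-component chemical/semantic similarity, and generate ranked,
novel hypotheses by recombining relation contexts between similar
substances.

The package is for text-mining and drug-repurposing researchers who want
a transparent, fully inspectable implementation of Swanson-style
undiscovered-public-knowledge mining — every stage is a plain function
over data frames, every intermediate artifact is a human-readable text
file, and a seeded synthetic-corpus generator makes the whole pipeline
runnable and testable with no external downloads, parsers or ontology
servers.

## The model

A sentence mentioning an effect word (*induce*, *contribute*, *increase*
→ Increase; *reduce*, *resistant* → Reduction) is viewed as a graph:
words are vertices, typed links are edges. An extraction rule is the
shortest path from the effect word to a concept, e.g.

```
induc :: S- @SUBSTANCE          # follow an S link leftward to the substance
induc :: MV+ (in) J+ @BODYPART  # rightward via "in" to the body part
```

Rules are learned from tagged example sentences and matched against new
parse graphs; a lexicon-backed recognizer types the extracted spans,
drops unknowns and repairs mis-slotted concepts before relations are
assembled.

Substance pairs are scored with

```
sim(a, b) = s_type + s_struct + s_atomic + s_xlogp,   each in {0, 0.5, 1}
```

where `s_struct` maps the MCS-Tanimoto `t = m / (|a| + |b| - m)` (`m` =
atoms in the maximum common connected subgraph) through comparative
bands, `s_atomic` compares element counts by relative Manhattan distance,
and `s_xlogp` bands the partition-coefficient difference. The maximum is
4; pairs scoring at least 2 (default threshold) recombine: each substance
inherits the partner's (process, disease, body part) context, duplicates
of extracted relations are dropped, and hypotheses are ranked by score.

## Worked example

Using the small corpus shipped under `inst/extdata` (four abstracts,
their parse graphs, a rulebook learned from two tagged sentences, a
semantic lexicon and a chemical table):

```r
library(upkminer)
ex <- function(f) system.file("extdata", f, package = "upkminer")

rel <- run_extraction(ex("abstracts.xml"), ex("parses.pg"),
                      read_rulebook(ex("rules.txt")), ex("lexicon.tsv"))
rel[, 1:5]
#> # A tibble: 4 × 5
#>   substance       effect_type process                disease body_part
#>   <chr>           <chr>       <chr>                  <chr>   <chr>
#> 1 Fisetin         Increase    apoptosis              NA      HCT-116 cells
#> 2 Docetaxel       Increase    apoptosis              NA      NA
#> 3 Wogonin         Increase    apoptosis              NA      malignant T cells
#> 4 Tolfenamic acid Increase    Sp protein degradation NA      cancer cell lines
```

Wogonin and Fisetin both increase apoptosis, in different cell
populations. Their similarity (semantic types equal, reference structural
similarity 0.75, formulas C16H12O5 vs C15H10O6, XLogP 2.74 vs 2.77):

```r
chem <- read_chemical_records(ex("chem.tsv"))
structural <- readr::read_tsv(ex("structural.tsv"), show_col_types = FALSE)
glance(similarity_score(chem[1, ], chem[2, ], structural_similarity = 0.75))
#> # A tibble: 1 × 7
#>   name_a  name_b  semtype structural atomic xlogp total
#>   <chr>   <chr>     <dbl>      <dbl>  <dbl> <dbl> <dbl>
#> 1 Wogonin Fisetin       1          1      1     1     4
```

All four components score 1, total 4 — well above the threshold — so the
pair recombines, each substance inheriting the other's context:

```r
generate_hypotheses(rel, chem, structural = structural)[, c(1:3, 5:6)]
#> # A tibble: 2 × 5
#>   substance effect_type process   body_part         score
#>   <chr>     <chr>       <chr>     <chr>             <dbl>
#> 1 Fisetin   Increase    apoptosis malignant T cells     4
#> 2 Wogonin   Increase    apoptosis HCT-116 cells         4
```

The two generated rows are *novel*: neither five-field tuple occurs among
the extracted relations. The score column is the pair similarity and
drives the ranking.

A command-line front end with `learn-rules`, `extract`, `hypothesize`,
`pipeline`, `simulate` and `eval` subcommands is installed at
`system.file("scripts/upkminer", package = "upkminer")`.

Synthetic corpora with planted ground truth (and precision/recall
evaluation against it) come from `generate_corpus()` /
`evaluate_extraction()`; see the vignette in `vignettes/` for the methods
and design notes.

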