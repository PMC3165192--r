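---
title: "Mining undiscovered public knowledge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining undiscovered public knowledge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upkminer)
```

## The discovery model

Swanson's ABC model of undiscovered public knowledge observes that if one
literature reports "A affects B" and a disjoint literature reports "B occurs
in C", the implicit connection A–C may never have been published, yet is
already supported by public evidence. `upkminer` operationalizes a
substance-centred variant of this idea over biomedical abstracts:

1. **Extraction.** Sentences mentioning an *effect word* (induce,
   contribute, increase, reduce, resistant) are parsed into
   link-grammar-style graphs and matched against learned path rules to
   produce SEPDB relations — **S**ubstance, **E**ffect type, **P**rocess,
   **D**isease, **B**ody part. The effect node connects the relation: a
   substance's effect influences a process or a disease, which in turn may
   occur in a body part.
2. **Similarity.** Pairs of extracted substances are scored with a
   four-component similarity (semantic type, structure, atomic count,
   XLogP). Similar substances are presumed to act similarly.
3. **Recombination.** For a sufficiently similar pair, each substance
   inherits the other's relation context, generating ranked, novel
   hypotheses.

The package is organized so each stage is a data-frame-in/data-frame-out
function usable on its own; `run_pipeline()` chains them.

## Parse graphs and the rule layer

A parsed sentence is a graph whose vertices are words and whose edges are
typed links. The package does not parse natural language itself: it
consumes a line-based interchange format (`read_parse_file()`) that any
parser adapter can emit, and ships `toy_linker()`, a deterministic
template linker covering the generator's surface forms. Link labels are
stored *reduced* — only the upper-case primary type (`Ss` → `S`) — so
subscript variants satisfy the same rule.

A rule is the shortest path from an effect word to a tagged concept:

```
induc :: MV+ (in) J+ @BODYPART
```

reads "from a word stemming to *induc*, follow an `MV` link rightward to a
word stemming to *in*, then a `J` link rightward; the word reached (after
entity expansion) fills `@BODYPART`". Words are Porter-stemmed throughout
so inflection ("induces", "inducer") does not fragment the rule space; the
stemmer is implemented from the original published rule tables.

Design points the interchange contract fixes explicitly, since any drift
here silently corrupts rules:

* token indices are 0-based and spans are closed intervals;
* links are stored with `left < right`; a rule's `+`/`-` is resolved at
  traversal time relative to the current token;
* the head of a tagged concept span is its **rightmost** token (head-final
  noun phrases) and entity expansion runs leftward from the head;
* expansion traverses links in a configurable set, default `{AN, A, G}`
  (noun-modifier, adjective, name chains). Which links the original
  extraction stack expanded through is not documented anywhere we could
  find; this default keeps determiners and quantifiers (linked `D`) out of
  entity names while capturing compounds like "Sp protein degradation".
  It is a calibrated choice, recorded in `upk_config()`.

When several shortest paths tie during learning, the lexicographically
smallest (label, direction) sequence wins, making rulebooks reproducible.
During matching, *all* bindings of every applicable rule are kept (set
semantics): a concept can participate in many relationships, and
downstream deduplication absorbs the fan-out.

## The recognizer

A semantic lexicon file stands in for an ontology-backed named-entity
recognizer: it maps surface terms (case-folded, whitespace-squished; not
stemmed, so "HCT-116" survives) to one of SUBSTANCE / PROCESS / DISEASE /
BODYPART plus a semantic type string. Normalization then

* drops terms the lexicon does not know (unknowns inflate false
  positives),
* moves a term whose recognized group disagrees with the slot that caught
  it (a disease caught by a process rule is re-filed as a disease), and
* rejects assemblies violating the relation invariants: a substance must
  be present, and at least one of process/disease.

When a moved term would displace a term that natively belongs to a slot,
the native term wins and the moved one is dropped with a note. This
collision policy, and the fan-out of multi-candidate slots into one
relation per combination, are choices of this package; idempotence of
normalization is enforced by test.

## The similarity measure

For substances $a, b$ the score is

$$\mathrm{sim}(a,b) = s_{\mathrm{type}} + s_{\mathrm{struct}} +
s_{\mathrm{atomic}} + s_{\mathrm{xlogp}}, \qquad s_i \in \{0, 0.5, 1\},$$

so $\mathrm{sim} \in [0,4]$ in half-point steps, with 4 attained exactly by
a complete record against itself.

* **Semantic type** — 1 iff the two type strings match (case-folded).
* **Structure** — the MCS-Tanimoto $t = m/(|a|+|b|-m)$, where $m$ is the
  atom count of a maximum common *connected* subgraph under
  element-and-aromaticity matching, bond orders ignored. $t \ge 0.75$
  scores 1; otherwise a substructure relationship ($m$ equal to the
  smaller molecule) scores 0.5; else 0. The 0.75 cut-off is calibrated so
  a printed reference value of exactly 0.75 counts as Similar.
* **Atomic count** — relative Manhattan distance between element-count
  vectors, $d = \sum_e |a_e - b_e| / \max(n_a, n_b)$; $d \le 0.2$ scores
  1. No published rule exists for this component; 0.2 is calibrated so
  both printed worked pairs (distances 3/32 and 4/33) count as Similar
  while unrelated molecules do not.
* **XLogP** — absolute difference $d$: $d \le 0.5$ scores 1,
  $0.5 < d < 1$ scores 0.5, $d \ge 1$ scores 0. The source table prints
  the middle band as "(1 < diff <0.5)", which is vacuous as written; the
  reading implemented here is the only one consistent with both printed
  examples. Boundaries go to the friendlier band at 0.5 and to 0 at 1.0.

The MCS search is a McGregor-style backtracking extension growing a
mapping only through pairs that share a common bond, so connectivity holds
by construction; expansion order is deterministic. A step budget
(`mcs_max_steps`, default $2\times10^6$ search nodes) caps worst-case
inputs, in which case the result is flagged as a lower bound rather than
silently wrong. Tests verify exactness against an independent exhaustive
enumeration oracle on all pairs of fixture molecules up to 12 heavy atoms.

Where a reference tool's printed structural similarity exists for a pair,
it can be supplied (`structural_similarity =`, or the `structural` table
of `candidate_pairs()`) instead of recomputing: different MCS flavours
(atom-only vs atom+bond Tanimoto) legitimately disagree, and the printed
value is then the ground truth for that pair. Missing record fields
degrade their component to 0 with a warning rather than failing the pair.

## Hypothesis generation

Candidate pairs are unordered pairs of extracted relations with distinct
substances, the *same* effect type, chemical records for both, and
similarity at or above the threshold (default 2). Pairing across opposite
effect types is deliberately unsupported: no worked example exhibits it,
and transferring a context across an effect reversal would change the
claim's meaning.

Recombination transfers the partner's **full** (process, disease, body
part) context, not the body part alone. The narrower body-part swap
described alongside the worked example is the special case of identical
processes; published sample output contains a generated relation whose
process is foreign to the substance's own extraction, which only the
full-triple transfer produces. Candidates equal to their own parent or to
any extracted relation are dropped (novelty contract, exact five-field
equality after case/whitespace normalization — no synonym resolution).
If the same five-field hypothesis arises via several partners, the
maximum pair score is kept. Ranking is score-descending with
lexicographic tie-breaks, so output order is a pure function of the input
set.

## The synthetic corpus generator

`generate_corpus()` emulates all five pipeline inputs with planted ground
truth: abstracts realizing each planted relation through one of three
surface templates ("X induces Y in Z", "X was a potent inducer of Y",
"X reduces Y"), parse graphs from the template linker, tagged training
blocks (first occurrence of each verb/template shape), a covering
semantic lexicon, and a chemical table generated in pairs — a tunable
fraction (`similar_fraction`, default 0.5) share a scaffold (one member
is the other plus one appended carbon, hence a guaranteed substructure),
matching semantic types, formula perturbation under the atomic threshold
and XLogP jitter within 0.5, so the similarity stage has known positives.
Noise adds distractor sentences, half with no effect word and half with
an effect word but an out-of-lexicon substance (which the recognizer must
reject); planted sentences are never corrupted, so recall is weakly
monotone under noise and precision stays 1. All randomness derives from
the single seed; regeneration is byte-identical.

What the generator does *not* emulate — and therefore what perfect scores
on it do not demonstrate: real parser errors and unparseable sentences
beyond template misses, anaphora and cross-sentence relations, lexical
ambiguity and synonymy, structured-abstract section headers, and the
long-tailed vocabulary of real MEDLINE text. Recovering 100% of planted
relations shows the learn/match/normalize contracts are self-consistent,
not that real-corpus recall would be high.

Test problem sizes are chosen to exercise the contracts while keeping the
suite quick: end-to-end recovery uses 50 planted relations across 5
seeds; the MCS oracle comparison covers all pairs of 11 fixture molecules
(≤ 12 heavy atoms); noise monotonicity uses 12–16 relations at three
noise levels over two seeds.

## Degenerate inputs and numerical corners

* Empty abstracts yield no sentences; an empty corpus is a valid corpus.
* A sentence whose route cannot be completed is a non-match, not an
  error; a concept unreachable from the effect word at *learning* time is
  an error, since the tagged example is then unusable.
* `evaluate_extraction()` reports undefined precision/recall (empty
  denominators) as 0 with an explicit `*_defined = FALSE` flag.
* Scores are sums of four exact halves, so equality comparisons on totals
  are safe; no floating-point tolerance is needed anywhere in the
  measure.
* Stemming a stem is almost always a fixed point; the few exceptions
  ("agre") do not affect matching because all matching is single-pass
  against a lexicon stemmed once at load.

## Worked example

```{r example}
ex <- function(f) system.file("extdata", f, package = "upkminer")
rules <- read_rulebook(ex("rules.txt"))
rel <- run_extraction(ex("abstracts.xml"), ex("parses.pg"), rules,
                      ex("lexicon.tsv"))
rel[, 1:5]

chem <- read_chemical_records(ex("chem.tsv"))
structural <- readr::read_tsv(ex("structural.tsv"), show_col_types = FALSE)
wf <- similarity_score(chem[chem$name == "Wogonin", ],
                       chem[chem$name == "Fisetin", ],
                       structural_similarity = structural$t[1])
glance(wf)

generate_hypotheses(rel, chem, structural = structural)[, 1:6]
```

## Known limitations

* The rule layer has no generalization or weighting: every rule is an
  exact path, and coverage is bounded by the tagged examples.
* The recognizer is a lexicon lookup with a suffix fallback; no word-sense
  disambiguation, no abbreviation expansion.
* XLogP is consumed, never computed; structure handling ignores bond
  orders, charge and tautomerism, and the SMILES subset omits full
  stereochemistry.
* Hypotheses are pairwise recombinations; multi-hop chaining
  (A→B→C transitivity) is out of scope.
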