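---
title: "Mining primer and probe sequences from full-text articles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining primer and probe sequences from full-text articles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerminer)
library(tibble)
```

PCR primers and hybridization probes are validated, published and then
buried in the running text and tables of methods sections. `primerminer`
extracts them: it models a full-text article as a section tree, scans the
main-content sections with a cascade of three sequence detectors over the
degenerate IUPAC nucleotide alphabet, cleans the raw matches with a small
forward-chaining rule base, and links the surviving sequences to organism
and gene names scored by document evidence. This vignette explains each
stage, the tunable parameters, and the design decisions taken where the
procedure left genuine choices open.

## The document model

A parsed document is a tree of typed sections: `paperTitle`, `authors`,
`abstract` (with `subAbstract` children), body sections at three named
nesting levels, `minorSection` for acknowledgements and references, and
`table` / `figure` nodes. Two properties matter downstream:

* **Reading order.** Depth-first pre-order over the tree reproduces the
  logical reading order, so concatenating section texts reconstructs the
  document. For plain-text input the whole document is stored in a single
  body section (a warning notes that skipping sectioning can cost
  accuracy, because text from otherwise-excluded regions is scanned too).
* **Floating material.** Tables and figures attach directly to the root,
  wherever they sit in the source markup: in print they are often placed
  away from the section that references them, and one table may be
  referenced from several sections. We append them after the body children
  of the root; their exact slot in reading order is a convention (the
  procedure itself does not prescribe one), and nothing downstream depends
  on it beyond determinism.

Table grids are flattened left-to-right, top-to-bottom into a single
string, with cells joined by the artificial delimiter `" @ "`. The
delimiter was chosen because `@` is outside the sequence alphabet *and*
outside every separator the detectors tolerate, so no detector match can
ever span two cells (or two rows — row boundaries use the same
delimiter).

```{r}
flatten_table(list(c("Stx1", "GTA CGT CTT", "35"), c("Stx2", "73.5")))
```

Only the main-content section types — the three body levels, tables and
figures — are fed to the detectors; title, authors, abstract and minor
sections are discarded, since primer sequences are reported in methods
text and tables, and scanning boilerplate only adds noise.

## The alphabet and the detector cascade

Printed primer sequences use the IUPAC degenerate code: the four bases
plus eleven wildcards, each naming a set of permissible nucleotides
(`K` = G/T, `N` = any, ...), in either letter case. The working alphabet
therefore has exactly 30 symbols. `expand_symbol()` exposes the
wildcard-to-base sets and `reverse_complement()` the complement table.

Three detectors scan each eligible section, in decreasing order of
specificity; a span claimed by a higher-priority detector is masked before
the lower ones run, so claims never overlap and the detector id doubles as
a confidence grade:

1. **Delimited** (`detect_delimited()`): runs of alphabet symbols —
   blanks, dashes and newlines allowed inside — opened by `5'`, `3'`, `5`
   or `3` and optionally closed by the complementary delimiter. The prime
   is optional. The opening delimiter must abut the sequence directly or
   via a dash: in reference material, a space-separated `3' AAGCT ...` is
   recognised by the generic detector instead, so attachment is part of
   this detector's definition here.
2. **Triplets** (`detect_triplets()`): at least three whitespace-separated
   groups, all of exactly three symbols except a final group of up to
   three — the common codon-style table rendering.
3. **Generic** (`detect_generic()`): maximal stretches of alphabet runs
   joined by blanks, dashes, colons or newlines. No minimum length is
   imposed (junk as short as a single letter is left to the refiner, which
   is the component designed to discard it); a `min_span_symbols` option
   exists for throughput tuning but defaults to the faithful value 1.

The detectors are implemented as deterministic left-to-right longest-match
scanners satisfying those pattern definitions; we make no claim about
equivalence to any particular automaton presentation of the same patterns.

Matched regions are tokenized into maximal alphabet runs; blanks, dashes
and newlines are dropped, while each colon becomes its own `":"` token
because the refinement rules split on it (colon-attached labels like
`F:` are a recurring artefact).

```{r}
tokenize_region("CGT CCM\nARR-GGA-WAC-TGA")
doc <- suppressWarnings(parse_plain_text("MY 09, 5-CGT CCM ARR GGA WAC TGA TC-3; where M = A/C", "demo"))
scan_document(doc)[, c("detector", "tokens")]
```

## Rule-based refinement

Raw candidates suffer three ailments: prose words spelled entirely over
the alphabet (`and`, `standard`, `DNA`), residual affixes such as the
TAMRA dye label printed after probes, and pairs of sequences merged across
a linking word. Eight rules, fired to fixpoint in strict priority order,
repair all three:

| rule | action |
|------|--------|
| R1 | discard facts with fewer than `l_min` symbols in total |
| R2 / R3 | strip a problem affix matched at the tail / head |
| R4 | discard facts whose every token is a dictionary word |
| R5 | split a fact around a problem affix matched strictly inside it |
| R6 / R7 | drop a leading / trailing dictionary word of length ≥ 3 |
| R8 | concatenate the remaining tokens into one refined sequence |

Parameters and conventions:

* `l_min` defaults to 7 symbols, the shortest query at which a
  sequence-similarity lookup still returns useful results. The rule
  discards *strictly shorter* facts, so a 7-symbol sequence survives.
* Conflict resolution: rules in priority order R1 > ... > R8; within a
  rule, facts in insertion order (FIFO), with facts produced by a firing
  appended at the end. We validated this pair of tie-breaks by hand
  against the reference refinement traces, including the long
  thirteen-token example whose trace discriminates between alternatives.
* `affix_within_sequence()` selects the *longest* interior match, ties by
  earliest position. The documented tie rule only covers equal lengths;
  longest-first is the only reading consistent with the reference traces.
* R8-refined facts are terminal: they leave the active set, which is what
  makes the firing count strictly bounded (every rule strictly decreases
  the active token count, so a fact base with *n* tokens fires at most
  *n* rules).
* A fact emptied by stripping is discarded silently.
* Dictionary and affix matching are case-insensitive; sequence content is
  never re-cased.

The problem-affix list and the problem-word dictionary are configurable
(`refiner_config()`, `read_dictionary()`, `read_affix_list()`). The
bundled seed lists are small curated reconstructions: each affix
(`TAMRA`, `TAMRA T`, `and`, `:`, `R :`, `F :`) and the load-bearing
dictionary entries (`and`, `than`, `standard`, `strand`, `assay`, ...)
are directly evidenced by reference refinement behaviour. `DNA` and `RNA`
are deliberately *excluded* from the dictionary: the reference traces
discard `{"DNA"}` by the length rule and `{"RNA","strand"}` by
R7-then-R1, which is only possible if neither token is a dictionary word.
Users with different corpora should extend both lists via the config.

```{r}
refine_tokens(c("TTCTTTTGGTGGACGATGTG", "and", "GAGGGACGC", "TTGGTAACG", "TAMRA",
                "and", "TCGCAAGCC", "AAGCAAATAC", "TAMRA", "T", "and",
                "GAGATAGGGTGCGATGGTTG", "TCGGCGATGACTACGACA"))
```

## Organism and gene annotation

Refined sequences are passed to a *lookup backend*: any function mapping a
sequence to ranked hits, each with a record identifier, an organism name
and optional gene names. In production this would front a local mirror of
a nucleotide database (public endpoints throttle or ban bulk queries, and
full records are megabytes when only two names are needed); the package
ships a tibble/TSV-backed implementation (`lookup_backend()`,
`read_lookup_tsv()`) with exactly the same contract. Only the top 10 hits
are consulted per sequence.

Each hit is then scored against the document itself:

* **Variants.** For an organism name of `L` words we generate every
  leading-word prefix and, for multi-word prefixes, the genus-abbreviated
  form (`B. melitensis`). Abbreviation does not reduce a variant's
  covered-word count `l` — an abbreviated binomial is as specific as the
  spelled-out one. The full name itself is included (a harmless superset
  of the shorter variants). Unlike ordinary English noun groups, organism
  names gain specificity from *post-positive* words, which is why
  prefixes are the right variant family.
* **Matching** is case-insensitive, whole-word and punctuation-tolerant,
  over every section's title and text. `l` is the covered-word count of
  the longest matched variant; co-occurrence asks whether some match of
  that length shares a section with the sequence.
* **Organism score.** `CS_L(l) = 100 − 60·(L − l)/(L − 1)` for `L ≥ 2`
  (100 for a one-word name), 0 when nothing matched, plus a 20-point
  co-occurrence bonus, capped at 100. The reference description fixes the
  anchor `CS_3(2) = 70`, the endpoints (full match scores 100) and
  monotonicity, but not the analytic form between them; we pin the linear
  interpolation with `CS_L(1) = 40` as the simplest curve satisfying all
  the stated constraints, and freeze it so tests are deterministic.
* **Gene score.** 80 points if the gene name appears anywhere in the
  text, plus 20 if it co-occurs with the sequence in the same section,
  else 0.
* Among the top hits, the one with the highest organism score wins (ties
  to the earlier hit); among the winning hit's gene names, the
  best-scoring one is reported (ties to the first). Document evidence is
  thus the arbiter between equally-ranked database hits.

```{r}
organism_confidence(L = 3, l = 2)                  # base score
organism_confidence(L = 3, l = 2, cooccurs = TRUE) # with the section bonus
plot_confidence_curves(L = 2:6)
```

## Evaluation and the synthetic corpus

`evaluate_detection()` scores extracted sequences against a gold standard
by exact, case-sensitive string identity within a paper — the evaluation
unit is "this sequence was reported in this manuscript", so order and
repeated occurrences are irrelevant. Precision and recall are reported as
percentages, the F-measure as `2PR/(P+R)`.

Because the original evaluation corpus is a set of copyrighted full-text
articles, the package ships a generator (`generate_fixture()`) that builds
small articles — each rendered both as plain text and as JATS XML — with
known ground truth:

* planted sequences in all three representation patterns, with optional
  line-wrapping, `and`-merging of pairs and trailing `TAMRA T` labels,
  plus lowercase and degenerate-symbol variation at realistic rates
  (defaults: 6 documents, 2 sequences per pattern each, 25% wrapped, 10%
  lowercase, 10% with one wobble base; noise rates default to 0 and are
  switched on explicitly by tests that target the refiner);
* distractor prose whose alphabet-only runs are either shorter than
  `l_min` or dictionary words, so a correct pipeline scores 100%
  precision and recall on clean corpora — that property is what the
  end-to-end tests assert;
* an organism per document (full name in the background, abbreviated form
  co-occurring with the sequences) and a gene name, mirrored in a lookup
  table so annotation can be exercised offline, with decoy hits pointing
  at an organism never mentioned in the text.

Everything is driven by one seed; the same seed yields byte-identical
corpora, and the pipeline itself contains no randomness, so runs are
reproducible end to end. The test suite works at desk scale — corpora of
3–6 documents, a few dozen planted sequences, 200-case property sweeps —
which keeps the whole suite under a minute.

What the fixtures do **not** emulate: PDF extraction artefacts (broken
reading order, hyphenation, headers/footers), OCR noise, journal layout
diversity, and the long-tail vocabulary of real prose. Passing the
synthetic suite therefore demonstrates the mechanics of detection,
refinement and annotation, not corpus-level accuracy on real articles;
on real text the curated dictionary and affix lists would need extending
(they are deliberately replaceable), exactly as relevance-feedback-style
maintenance would do in production.

## Known limitations

* PDF and HTML ingestion are out of scope; plain text and JATS-style XML
  are the two supported formats.
* The package does not discriminate primers from probes from other
  reported oligonucleotides; it extracts and annotates all of them.
* Plain-text input loses sectioning, so section co-occurrence degenerates
  to document co-occurrence and annotation scores can only rise.
* Very short genuine sequences (under 7 symbols) are discarded by design;
  lowering `l_min` trades recall against a flood of prose false
  positives.
* JATS nesting below the third body level is folded into the deepest
  named type, since the section-type vocabulary has three body levels.
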