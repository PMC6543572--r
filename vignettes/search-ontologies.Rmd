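---
title: "Search ontologies, generated queries and the reference engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Search ontologies, generated queries and the reference engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonq)
```

## The model

`sonq` models systematic literature screening around three kinds of
entities. *Search concepts* are the things whose descriptions must (or,
for negated concepts, must not) occur in a relevant document. *Search
terms* are their textual designations: simple terms (single words or
user-fixed phrases, per language) and composite terms, which combine the
OR-linked simple terms of two concepts with `AND` or a proximity
operator. *Search queries* are derived strings: each concept's single
concept query OR-joins all of its terms (negated concepts produce
`NOT (…)`), and a multiple concept query AND-joins the single concept
queries of selected concepts.

The assumptions behind this model are modest: that relevance can be
approximated by boolean co-occurrence of concept designations, sharpened
with proximity (token distance, sentence, paragraph) and term-type
control; and that a domain expert can enumerate the designations per
concept in a spreadsheet. Everything else is mechanical, which is the
point — query strings are never hand-written.

```{r}
d <- generate_all(build_niti_dson(), generation_options("en"))
d$composite_terms[[1]]$query$en
```

## Template encoding

The workbook has user-defined facet sheets plus the reserved sheets
`Negated_Concept`, `Composite_Term` and `Multiple_Concept_Query`. Some
encodings are not dictated by the sheet layout itself and were fixed as
follows.

* **Hierarchy.** The columns left of `Simple Terms (en)` are depth
  columns; a concept's name sits in exactly one of them, and its parent
  is the nearest preceding row whose name sits in a shallower column
  (the common spreadsheet-taxonomy dialect). `write_template()` emits
  rows in pre-order so the encoding is self-consistent.
* **Identifiers.** Cell text is normalized by trimming, replacing
  internal whitespace with underscores and capitalizing each word
  (`endoscopic clipping system` → `Endoscopic_Clipping_System`), matching
  the class-naming style of the generated ontology.
* **Term cells.** Terms are `;`-separated (phrases may contain commas),
  with a trailing `^k` parsed as a positive boost; `^0` or a non-numeric
  suffix is a cell-level error with its sheet/row location.
* **Negated concepts.** Per-language columns
  `Excluded Simple Terms (en)`/`(de)` are used; a legacy single
  `Excluded Simple Terms` column is accepted as English. An optional
  `Excluded Concepts` column (`;`-separated) lets a negated concept
  exclude the terms of standard concepts; without such a column that
  model field simply cannot be expressed in a workbook. Hierarchies
  beneath negated concepts are not supported — the sheet is a flat list.

## Query generation

Generation proceeds composite terms → single concept queries → multiple
concept queries, and is idempotent. Choices that the printed examples do
not fully determine:

* Negation is rendered `NOT (…)` rather than a `-` prefix, because `NOT`
  composes under the grammar.
* A `MODE/X` setting wraps the *whole* generated expression,
  `MODE/X ( … )`, mirroring the printed form `MODE/E (SafeSet)`.
* `NEAR` on a multiple concept query joins only the standard-concept
  sub-queries; negated concepts always attach with `AND`, since
  proximity to an excluded term is meaningless.
* Operand order follows spreadsheet order everywhere, operators are
  uppercase with single-space separation — so generated strings are
  reproducible byte-for-byte.
* A concept with no terms in a requested language yields a warning and
  no query in that language (`skip_empty_concepts = TRUE`, the default)
  rather than failing the whole run.

## OWL and JSON serialization

The base vocabulary is fixed at 9 classes (`Search_Concept`,
`Standard_Concept`, `Negated_Concept`, `Search_Term`, `Simple_Term`,
`Composite_Term`, `Search_Query`, `Single_Concept_Query`,
`Multiple_Concept_Query`) and 13 annotation properties (`described_by`,
`has_part`, `has_terms_of_concept_as_part`,
`has_term_of_concept_as_part_1`, `has_term_of_concept_as_part_2`,
`has_query_of_concept_as_part`, `simple_term`, `composite_term`,
`query`, `excluded_concept`, `excluded_simple_term`, `mode`, `near`).
Terms and queries are language-tagged annotation literals on the
classes; `described_by`, `has_part` and `has_terms_of_concept_as_part`
are emitted as vocabulary for compatibility with the older
instance-based modelling style but are not instantiated. Facet
membership and the ontology's short name are not expressible in this
vocabulary; they travel as annotations in a separate fixed metadata
namespace (`http://son-generator.org/meta#`) so that the SON-namespace
census stays exactly 9 + 13 while `from_owl(to_owl(d))` remains an
identity.

RDF/XML is the canonical output syntax. On input, a Turtle subset is
also accepted (prefix declarations, `;`/`,` continuation, language-tagged
literals) — enough to read back tool-re-serialized documents and
external label ontologies, which `import_external_ontology()` turns into
facets (labels become terms; a label-less class falls back to its local
name; diamond superclasses attach to the first parent, with a warning).

In the JSON export each facet is a tree of nodes with the fixed key
order `name, type, simple_terms, query, children`; composite terms
appear as `composite_term` children of their owning concept, and terms
are rendered in query-fragment form (quotes for phrases, `^k` boosts) so
the strings are directly usable. The shape is described by the schema
shipped at `inst/extdata/dson-schema.json`, and `validate_json()`
implements the subset of JSON Schema that schema uses.

## The query engine

The grammar's precedence, low to high, is
`OR < AND < NOT < NEAR < MODE < atom`; operators are case-sensitive
uppercase, `NEAR` is binary and left-associates. The parser records the
number of explicit parenthesis layers on each node, so
`render_query(parse_query(s))` reproduces `s` exactly — the closure
property that guarantees every generated string survives a round trip
through the engine.

Evaluation is span-based. Every node yields a match flag, a score and a
set of half-open token intervals:

* **Term types.** The default mode is `D` (case-folded,
  diacritics-stripped), because exact surface matching (`MODE/E`) is the
  restrictive opt-in. `B` compares lexicon baseforms and falls back to
  `D` when the lexicon is silent; `C` additionally matches compound
  parts and degrades to no splitting without a lexicon. Wildcards
  (`*`, `?`) match against the active mode's representation.
* **Proximity.** The `NEAR/k` gap is the minimum token distance between
  the closest endpoints of a span pair — adjacent tokens have gap 1, and
  overlapping spans have gap 0 (so a nested `NEAR` hull can satisfy an
  enclosing one). A `NEAR` node's own span is the hull of the two chosen
  spans. `NEAR/S` and `NEAR/P` require both spans to lie inside one
  sentence or paragraph; a span that straddles a boundary qualifies for
  neither. `NOT` is rejected as a `NEAR` operand.
* **Scoring** is a deliberately minimal boost-sum: each distinct matched
  term or phrase occurrence contributes its boost (default 1). Ranking
  quality (BM25 and friends) is out of scope; the scores exist to make
  boosts observable and ties reproducible (ties rank by document index).
* **Tokenization** splits paragraphs at blank lines, sentences at
  `.!?` followed by whitespace (no abbreviation handling — a regex
  heuristic, adequate for screening but not linguistics), and tokens at
  whitespace/punctuation with intra-word hyphens kept.

Degenerate inputs are defined rather than errors: an empty document
matches nothing, `NOT x` matches a document without `x`, and an
unmatched query scores 0.

## Synthetic corpora and what the tests show

`build_corpus()` generates seeded documents from a filler vocabulary
that is disjoint from every fixture term, planting target words at
*exact* token gaps and controlled sentence/paragraph placements — so
ground-truth labels follow from the recipe arithmetic, independently of
the engine. Proximity corpora drive the `NEAR` checks (220 documents in
the default test run); mixed-ingredient corpora drive the end-to-end
screening check (60 documents); serialization round-trips run on 100
randomized ontologies and the evaluator is compared against a
brute-force oracle on 1000 random query/document pairs. These sizes keep
the default suite fast while leaving the generators free to scale up.

Synthetic text emulates co-occurrence structure only: real clinical
prose has abbreviations, inflection beyond the demo lexicon, section
headers and OCR noise, none of which the generator mimics. Passing tests
therefore demonstrate the correctness of the query semantics, not
retrieval quality on real literature.

## Known limitations

* Languages are limited to English and German, as in the template.
* No OWL reasoning; subclass structure is mirrored syntactically.
* The engine is a per-document reference evaluator, not an inverted
  index; corpora of thousands of documents are fine, web scale is not
  the goal.
* The `B`/`C` modes are only as good as the supplied lexicon; the
  bundled one is a small demonstration set.
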