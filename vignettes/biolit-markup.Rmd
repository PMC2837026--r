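---
title: "Inline semantic mark-up of biomedical text: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inline semantic mark-up of biomedical text: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biolitmark)
```

## The problem

Machine-readable metadata in the life-sciences literature is scarce because
adding it after publication is hard and error-prone; the most reliable
curator of a manuscript's meaning is its author, at writing time.
`biolitmark` implements the batch core of that idea: it recognizes
ontology terms (from locally supplied OBO files) and biological database
accessions (PDB, UniProtKB, GenBank, RefSeq) in a document, lets
ambiguities be resolved explicitly, and embeds the result as inline
NLM/JATS mark-up that survives round-tripping and coexists with mark-up
added by other tools.

Two element types carry the annotations:

* ontology terms:
  `<named-content content-type="biolit" id="ncbo_id=X;term_id=Y:Z;term=Q;url=http://H">Q</named-content>`
  — the `id` attribute packs the ontology registry id, the term CURIE, the
  preferred name, and an optional browse URL; the element content is the
  manuscript wording;
* database identifiers:
  `<ext-link xlink:href="..." ext-link-type="pdb">1MU2</ext-link>`.

The `url` field is optional. The `id` grammar is emitted in the fixed
field order above; on parsing, any field order is accepted, and a biolit
element whose `id` string does not parse is demoted to an opaque foreign
tag with a warning rather than dropped.

## Term recognition

Recognition is dictionary-based. `build_index()` collects every preferred
name and every synonym of every non-obsolete term of the active
ontologies into a map from *normalized surface form* to candidate terms.
All synonym scopes (EXACT/BROAD/NARROW/RELATED) participate: synonyms
exist precisely because preferred labels such as
"Leukemia, T-Cell, HTLV-II-Associated" rarely appear verbatim in prose,
so excluding scopes would only reduce recall.

`recognize_terms()` then reports every occurrence of an indexed form
subject to three rules:

* **Normalization.** Comparison is case-insensitive and internal
  whitespace runs (including a single line break, as in wrapped text)
  match a single space. Both choices maximize recall and are recorded in
  the index's `norm_policy`, and both are configurable; a run that wants
  case-sensitive matching sets `case_insensitive: false` in its
  configuration. A run of whitespace containing more than one line break
  (a paragraph boundary) does not bridge a multi-word term.
* **Token boundaries.** A match must be flanked by start/end of text or
  by a non-letter/non-digit character, so "leukemia" is not found inside
  "leukemias". No sentence segmentation is applied beyond this.
* **Non-overlap.** Inline tags cannot overlap, so overlapping occurrences
  are resolved longest-match-first with ties broken by leftmost start.
  This is a deliberate priority rule for a situation where no canonical
  rule exists; it guarantees a deterministic, maximal, non-overlapping
  annotation set.

Ignore rules (a form everywhere, or a single occurrence by document id
and span) are applied *after* overlap resolution. The order matters:
filtering before resolution could let a previously shadowed shorter match
surface, so "ignoring more" could paradoxically add annotations.
Applying ignores last makes ignoring monotone — the annotation set can
only shrink — which is the behaviour a user expects from "stop
recognizing this term".

A span recognized in several ontologies (e.g. "leukemia" as a disease
and as a family-history diagnosis) carries all candidates; exactly one
must be chosen before mark-up is emitted. Resolution is never guessed:
it comes from a decisions list in the configuration (surface form →
term), from `resolve_candidate()` in code, or — only when explicitly
enabled with `auto_single` — automatically for spans with a single
candidate. Unresolved spans are counted and exported but never injected.

Phrasing the dictionary misses (e.g. "hairy T cell leukemia" when the
ontology only knows the HTLV-II term and its "(disorder)" synonym) can
be marked manually with `apply_custom_term()`, which attaches the chosen
term while preserving the manuscript wording as the element content.
`propagate_markup()` extends one resolved annotation to all other
boundary-aligned occurrences of the same surface form that do not
collide with existing spans.

Offsets throughout are 0-based half-open character offsets, the standoff
annotation convention, which makes the TSV exports directly comparable
with other standoff tooling.

## Identifier recognition

Accessions are matched with seven fixed regular expressions (one PDB,
two UniProtKB, three GenBank, one RefSeq; see `db_patterns()`).
Identifiers are expected to be preceded by whitespace (or start of
text); we additionally require the match to end at a non-alphanumeric
character or end of text, so `in1MU2x` and `1MU2x` match nothing while
`1MU2.` matches. The right-boundary rule is our choice — only the left
boundary is forced by the convention that identifiers follow a space —
and it exists to prevent matches inside longer tokens. Matching is
uppercase-only; accessions are case-sensitive strings, not words.

A token matched by patterns of several databases (e.g. `A12345`, which
is both a valid UniProtKB and GenBank accession shape) yields a single
match carrying both candidate labels, resolved through the same
decisions mechanism as term ambiguity. The PDB link template is the
canonical structure-explorer URL; the UniProtKB/GenBank/RefSeq templates
are non-normative defaults and configurable, since no canonical template
is mandated for them.

Two printed-pattern transcription details are documented deviations: the
PDB pattern is implemented as `[1-9][A-Z][A-Z0-9]{2}` (validated by the
1MU2 example), and pipe-delimited character classes such as `[A|O|P|Q]`
are read as plain letter sets, because no real accession can begin with
a literal `|`.

## Mark-up carrier and round-tripping

The carrier is plain text or a JATS-like XML fragment, not a word
processor file: the elements are NLM/JATS inline elements, so the
dialect transfers unchanged to any JATS workflow. `parse_markup()` wraps
the fragment with a root that declares the `xlink` namespace;
`serialize_markup()` emits a bare fragment so that elements appear in
exactly their canonical byte form.

A `marked_document` is the plain text plus an ordered, pairwise-disjoint
set of spans. Three invariants are enforced and tested:

* **Text conservation** — stripping all tags from the serialization
  recovers the text character for character (XML specials are escaped on
  emit and unescaped on parse).
* **Round trip** — `parse_markup(serialize_markup(d))` reproduces `d`,
  and re-serializing reproduces the canonical bytes.
* **Foreign mark-up preservation** — elements this package does not own
  (anything that is not a well-formed biolit `named-content` or an
  `ext-link`) are kept as opaque spans and written back verbatim, so
  annotations added by other tools survive every pass.

Three boundary cases are worth knowing. Foreign elements are stored as
their libxml2 serialization: for canonically quoted input (which
includes everything this package or its fixture generator emits) that is
byte-identical; unusual quoting is normalized once, on first parse.
Mark-up nested *inside* a foreign element stays part of that opaque
span; only top-level elements are interpreted. An empty element
(`<break/>`) encloses no text and therefore cannot be represented as a
span over the text; such elements are not preserved, a known limitation
of the span model.

Injection (`inject_markup()`) refuses overlap: new spans overlapping
each other are an error; a new span overlapping an existing one is
skipped and reported. Because already-marked spans are "existing",
running the pipeline on its own output adds nothing — idempotence falls
out of the overlap rule rather than being a special case.

## The pipeline and its report

`run_pipeline()` wires the stages together: load and validate
ontologies, build the index, parse existing mark-up, recognize terms and
identifiers, drop occurrences already covered by existing mark-up,
apply ignores, apply decisions and `auto_single`, inject, serialize.
The report satisfies `recognized = resolved + ignored + unresolved` for
terms and identifiers separately; occurrences under pre-existing mark-up
are excluded from `recognized` (they were handled in an earlier pass).
There is no randomness anywhere in the pipeline; identical inputs give
identical output.

## Ontology handling

`parse_obo()` reads the OBO 1.2 subset that recognition and navigation
need: `[Term]` stanzas with `id`, `name`, `synonym`, `is_a`,
`is_obsolete`, `def`. Everything else is ignored without error — the
recognizer consumes labels and hierarchy, nothing more. Obsolete terms
are parsed but excluded from the index by default (their labels would
produce misleading mark-up); `include_obsolete` re-enables them.
Registry metadata (`ncbo_id`, browse-URL template) is not part of the
OBO format and comes from the run configuration, defaulting to empty.

`validate_ontology()` reports dangling `is_a` targets, `is_a` cycles,
obsolete terms and empty names; an ontology is usable iff it is acyclic
with no empty-name live terms (dangling references are tolerated, as
subset extracts often have them).

Hierarchy display is single-parent: `path_to_root()` follows, at each
level, the lexicographically smallest resolvable parent. Multiple
parentage is real in ontologies, and any single-path display of it is
incomplete; the lexicographic rule is an explicit, deterministic
stand-in, not a semantic claim. `search_terms()` is substring search
over names and synonyms with exact matches ranked first — deliberately
minimal; fuzzy matching is out of scope.

## The fixture generator

`gen_ontology()` / `gen_document()` exist so that every behaviour is
testable without downloading a real ontology. They emulate the
*mechanics* of the task — labels with synonyms and an acyclic `is_a`
DAG; documents with terms, multi-word forms, ambiguous forms shared
across two ontologies, valid accessions, and near-miss decoys
(`1MU2x`, lowercase accessions, pluralized labels) — under a fixed
filler vocabulary chosen to be disjoint from every generated label, so
the planted spans are provably the only recognizable content and ground
truth is exact by construction. Generation is a pure function of the
seed.

What the generator does **not** emulate: real literature statistics,
real ontology scale (hundreds of thousands of terms), nested or
overlapping natural phrasing, non-ASCII text, or genuinely ambiguous
context. Passing the fixture suite therefore demonstrates correctness
of the matching, resolution and round-tripping machinery — not recall
on real manuscripts, which is bounded by how well ontology labels match
authors' actual wording.

Default test problem sizes, chosen as comfortable desk-scale checks: 8–12
terms per ontology, 40–120 filler words per document, 100 documents for
round-trip properties, 20–25 seeded fixtures for ground-truth agreement,
and the full enumeration of all identifier tokens of length ≤ 6 over a
15-character alphabet (≈ 12.2 million tokens) for the pattern oracle.

## Numerical and degenerate-input choices

* Empty text, empty index, or zero enabled databases recognize nothing
  and are not errors; an empty search query is an error.
* A label that normalizes to the empty string is skipped with a warning
  at indexing time.
* Zero-length spans are invalid everywhere.
* Candidate order is deterministic: ontologies in configuration order,
  databases in the fixed order pdb, uniprotkb, genbank, refseq.
* `resolve_candidate()` takes 1-based indices, as R users expect.
* Duplicate term ids in one OBO file are a parse error naming the line;
  duplicate surface forms across terms are, by design, not an error but
  an ambiguity.

## Known limitations

* Recognition is exact (post-normalization) string matching: no term
  normalization, no heuristic synonym expansion, no context
  disambiguation. These are the natural next steps but they change the
  precision/recall trade-off qualitatively and are deliberately out of
  scope.
* Only `is_a` relationships are consumed; other relationship types are
  ignored.
* The span model is flat: overlapping or nested annotations cannot be
  expressed, matching the non-overlap rule of the mark-up dialect.
* Identifier patterns validate shape, not existence; no remote database
  is consulted.
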