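---
title: "From JATS and text annotations to Bioschemas markup: the model and its design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From JATS and text annotations to Bioschemas markup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioschemarkup)
```

## The problem

Publishers expose scholarly articles as JATS XML — machine-readable, but
with no shared semantics a search engine can act on. schema.org markup
embedded in pages is the lightweight alternative, and Bioschemas profiles
make it usable in the life sciences by fixing, per entity type, which
properties are *minimum*, *recommended* or *optional*. This package
implements that mapping for literature: bibliographic metadata plus
ontology-term annotations recognized in the text, emitted as one JSON-LD
graph per article.

## The entity graph

`build_markup()` produces a `markup_document` with four parts:

1. **Record node** (`schema:CreativeWork`). The structured-data
   representation is kept separate from the publication it describes and
   points at it via `schema:mainEntity`. This separation matters because
   properties of the structured data (how it is partitioned, when it was
   generated) are not properties of the article; schema.org offers too
   few CreativeWork properties to overload one node with both roles. The
   record node is therefore also exempt from profile validation — it is
   plumbing, not content.
2. **Article node** (`schema:ScholarlyArticle`), populated by a fixed
   mapping from JATS elements (title, contributors, abstract, dates,
   pagination, identifiers, license, references). One naming wrinkle is
   resolved here: the publication type is `ScholarlyArticle`, the name
   that actually exists in the schema.org vocabulary.
3. **Periodical chain**: `PublicationIssue → PublicationVolume →
   Periodical` through `schema:isPartOf`. Only the levels present in the
   input appear; the chain is re-linked so it is always contiguous and
   always terminates at the `Periodical`. All four volume/issue presence
   combinations are exercised in the tests.
4. **Annotation nodes** (`schema:DefinedTerm`), one per distinct term,
   linked reciprocally: the article's `schema:about` lists every
   annotation node and each node's `schema:subjectOf` points back. This
   bidirectional closure is a hard invariant — `serialize_jsonld()`
   refuses documents that violate it.

schema.org has no annotation type, so `DefinedTerm` is the closest
schema-native carrier: the ontology class IRI goes into `sameAs`, the
ontology namespace into `inDefinedTermSet`, and the occurrence count into
the extension property `biotea:occurrences` (namespace
`https://biotea.github.io/ns#`, declared in `@context` whenever
annotations are present). Annotation node identifiers are
fragment-based per article (`#ann-1`, `#ann-2`, …) rather than the term
IRI itself: the same ontology term annotated in two articles must yield
two annotation nodes with different `subjectOf` targets.

## Profiles as data

Draft profiles are living community conventions: tier membership moves.
The registry is therefore a bundled, editable TSV
(`inst/extdata/profiles.tsv`), one row per profile/property/tier, loaded
at first use — updating tiers requires no code change. The shipped
defaults:

| profile | type | minimum | recommended |
|---|---|---|---|
| ScholarlyArticle | ScholarlyArticle | name, identifier, author, datePublished | description, isPartOf, pageStart, pageEnd, license, citation, about, url |
| Journal | Periodical | name | issn, publisher |
| Volume | PublicationVolume | volumeNumber | isPartOf |
| Issue | PublicationIssue | issueNumber | isPartOf |
| SemanticAnnotation | DefinedTerm | name, sameAs | inDefinedTermSet, subjectOf |

Validation semantics: a missing or *empty* (empty string, empty list)
minimum-tier property is an `error`; recommended-tier, a `warning`;
`conformant` means zero errors. Optional-tier omissions are reported (as
`info`) only on request via `include_optional = TRUE` — by default a node
carrying every minimum and recommended property validates to an empty
issue list, which keeps "conformant and complete" a meaningful,
reachable state. Issue order is (severity, property name), so reports
are deterministic.

## Reading the inputs

**JATS.** Elements are matched by local name, ignoring namespace
prefixes, because OAI responses vary in their namespace declarations;
the OAI-PMH `GetRecord` envelope is transparent (parsing a bare article
and the same article wrapped yields identical results). Where JATS
offers several publication dates, the electronic date (`epub`) wins,
then print (`ppub`), then document order; partial dates serialize at
their real precision (`"2019"`, `"2019-06"`, `"2019-06-19"`) — no
invented days. The first abstract element only is used, its paragraphs
joined with blank lines. Contributors are `contrib-type="author"` (or
untyped) entries; group authorship lands in `surname`. Citations are
best-effort structured (`label`, title, DOI, PMID) on top of a
whitespace-normalized `raw_text` that is always present.

**PubAnnotation.** Offsets are 0-based, end-exclusive, counted in
characters, and never converted silently; spans are bounds-checked
against the document text whenever the text is present, and violations
name the offending denotation id. Annotations are deliberately read from
frozen files rather than a live annotator: annotator output drifts with
ontology releases, and reproducible markup needs a fixed annotation set.
Terms may be CURIEs; `expand_term()` resolves them against a
configurable prefix map (unknown prefixes pass through verbatim, with a
warning). Aggregation is by expanded term IRI, ordered by occurrence
count descending with byte-wise IRI order breaking ties, so downstream
node order — and hence the serialized bytes — is fully determined.
`ontology_hint` is derived from the IRI namespace (text up to the last
`/`, `#` or `_`); annotation inputs do not record their source ontology
explicitly, so this is best-effort by construction.

## Deterministic serialization

`serialize_jsonld()` emits a single object: `@context`, then `@graph`
with nodes in the order record, article, chain innermost-first,
annotations in aggregate order. Node keys are `@id`, `@type`, then
properties in byte-wise alphabetical order (locale-independent radix
sort). Output is 2-space-indented UTF-8 with LF line endings. Two
consequences are tested property-style: equal documents give
byte-identical text, and serialize → parse → serialize is a byte-level
fixed point. `embed_in_html()` splices the markup as the last child of
`<body>` as a `<script type="application/ld+json">` element — a string
operation, never a DOM re-serialization, so the surrounding page is
byte-preserved; placing machine-readable markup at the end of the page
keeps it out of the way of user-visible content.

## IRI minting

Node IRIs are `{base}/{article-id}#{fragment}` with fragments `record`,
`article`, `journal`, `volume`, `issue`, `ann-{i}`. The article id is the
first available of PMC id, DOI (with `/` replaced by `_` so the IRI
stays path-safe) and PMID; metadata with no identifier at all cannot be
minted and fails loudly rather than generating blank-node soup.

## The synthetic corpus — what it shows and what it cannot

The generators (`make_jats_fixture()`, `make_pubannotation_fixture()`)
emit the same dialects the readers consume, from one explicit seed each
with no global RNG state (the caller's `.Random.seed` is restored).
Content is lorem-style ASCII so span arithmetic is trivial; denotations
sit on alternating words, which makes spans disjoint and strictly
increasing by construction, and requested per-term multiplicities are
honored exactly. The test suite and the acceptance script run on: 100
seeded documents for the about/subjectOf closure, 100 annotation
fixtures for occurrence conservation and thresholding, 50 documents for
the serialization fixed point, 100 parameter vectors for the
generator/parser round-trip, and sitemaps up to 1,000 entries — sizes
chosen to exercise every code path many times while keeping a full run
in well under a minute.

What passing these suites does *not* show: robustness to the long tail
of real JATS (publisher-specific tagging, mixed-language records, deeply
nested inline markup), to annotation projects with overlapping or
discontinuous spans, or to Unicode-heavy text where byte/character
confusion would surface (offsets here are defined in characters; the
generated fixtures are ASCII, so that convention is asserted but not
stressed). The profiles' tier contents themselves are draft community
conventions, not measured facts — hence the editable table.

## Known limitations

- Full-text body structure (sections, figures) is out of scope; the
  markup covers metadata plus abstract-level annotations.
- Relation and attribute annotations of the PubAnnotation model are
  ignored; only denotations are counted.
- Validation is tier-presence checking against the five profiles, not
  SHACL/ShEx-grade shape validation, and does not attempt arbitrary
  third-party markup.
- No network retrieval: inputs are files (or generated fixtures) by
  design.
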