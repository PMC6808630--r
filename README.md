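# bioschemarkup

Scholarly literature repositories increasingly expose page-level structured
metadata so search engines can understand what an article is about — but
they usually stop at title, authors and journal, leaving out the
biomedical entities (genes, chemicals, diseases, processes) that text
mining recognizes in the article itself. `bioschemarkup` closes that gap:
it converts JATS-encoded article records (the XML dialect returned by the
PubMed Central open-access OAI-PMH interface) together with
PubAnnotation-format semantic annotations into schema.org/Bioschemas
JSON-LD markup, validates the result against the five draft Bioschemas
literature profiles, embeds it into HTML pages, and builds sitemaps so a
whole collection is crawlable. It is aimed at literature-repository
maintainers and text-mining groups who want their corpora to surface as
FAIR, machine-readable knowledge-graph nodes rather than opaque XML.

## The model

Each article becomes a small entity graph:

- a top-level `schema:CreativeWork` **record** node representing the
  structured data itself, linked to the publication via
  `schema:mainEntity` — keeping the markup separate from the article it
  describes;
- a `schema:ScholarlyArticle` node carrying the bibliographic mapping
  (`article-title → name`, `contrib → author`, `abstract → description`,
  `pub-date → datePublished`, `fpage/lpage → pageStart/pageEnd`,
  `article-id → identifier`, `license`, `ref-list → citation`);
- a containment chain `ScholarlyArticle → PublicationIssue →
  PublicationVolume → Periodical` via `schema:isPartOf`, with absent
  levels omitted and the chain re-linked contiguously;
- one `schema:DefinedTerm` node per distinct ontology term annotated in
  the text, holding the term IRI (`sameAs`), its ontology namespace
  (`inDefinedTermSet`) and an occurrence count
  (`biotea:occurrences`). Article and annotations are linked reciprocally:
  `schema:about` lists every annotation, and each annotation points back
  through `schema:subjectOf`.

Five tiered profiles (Journal, Volume, Issue, ScholarlyArticle,
SemanticAnnotation) define *minimum* / *recommended* / *optional*
properties per entity type; they ship as an editable table
(`inst/extdata/profiles.tsv`) and drive `validate_document()`: a missing
minimum property is an error, a missing recommended one a warning.
Serialization is deterministic — fixed node order, alphabetical keys —
so identical inputs always produce byte-identical JSON-LD.

Occurrence counting follows the annotation model of PubAnnotation: a
*denotation* binds a 0-based, end-exclusive character span to an ontology
term; denotations of the same expanded term IRI merge into one aggregate,
and a threshold (`min_occurrences = 2`, terms with more than one
occurrence) selects the terms prominent enough to surface.

## Worked example

Everything below runs offline: the package generates its own synthetic
JATS and PubAnnotation inputs.

```r
library(bioschemarkup)

art <- parse_jats(make_jats_fixture(seed = 7, n_authors = 3))
art
#> <jats_article> Aliqua ex laboris ipsum labore
#>   ids: PMC2628047 | 10.4975/synth.2628047.59 | 3371554
#>   authors: 3; citations: 2
#>   journal: Journal of Exercitation Research vol. 54 issue 8

set <- parse_pubannotation(make_pubannotation_fixture(
  seed = 7, term_multiplicities = c("GO:0008150" = 3, "CHEBI:15377" = 1)))
agg <- aggregate_terms(set)
agg
#> # A tibble: 2 x 5
#>   term_iri                              label   occurrences first_offset ...
#> 1 http://purl.obolibrary.org/obo/GO_00… 0008150           3            0
#> 2 http://purl.obolibrary.org/obo/CHEB…  15377             1           10
```

The sum of `occurrences` equals the number of denotations (here 4). Keep
terms with more than one occurrence, build the graph, validate:

```r
doc <- build_markup(art$metadata, art$periodical,
                    filter_by_occurrence(agg, 2),
                    policy = iri_policy("https://biotea.github.io/bioschemas"))
doc
#> <markup_document> Aliqua ex laboris ipsum labore
#>   article: https://biotea.github.io/bioschemas/PMC2628047#article
#>   chain:   PublicationIssue -> PublicationVolume -> Periodical
#>   annotations: 1

glance(validate_document(doc))
#> # A tibble: 1 x 5
#>   checked_nodes skipped_nodes n_errors n_warnings conformant
#> 1             5             1        0          0 TRUE
```

Five nodes are profile-checked (article, issue, volume, periodical and
the one surviving annotation); the record node is structured-data
plumbing and is skipped. `serialize_jsonld(doc)` then yields the
deterministic markup, starting:

```json
{
  "@context": [
    "https://schema.org",
    {
      "biotea": "https://biotea.github.io/ns#"
    }
  ],
  "@graph": [
    {
      "@id": "https://biotea.github.io/bioschemas/PMC2628047#record",
      "@type": "CreativeWork",
      "mainEntity": {
        "@id": "https://biotea.github.io/bioschemas/PMC2628047#article"
      }
    },
    ...
```

`embed_in_html(page, doc)` appends this as an
`<script type="application/ld+json">` element at the end of `<body>`
(byte-preserving the rest of the page), and
`build_sitemap(c("2628047"), "http://biotea.github.io/bioschemas")`
produces a sitemaps.org urlset whose entries follow the showcase URL
pattern `...?pmc=2628047`.

A command-line front end with `convert`, `validate`, `sitemap`, `embed`
and `fixture` subcommands lives at
`inst/cli/bioschemarkup.R` (`Rscript bioschemarkup.R convert --jats
article.xml --annotations ann.json --out markup.jsonld`); it exits 0 on
success, 1 on conformance failure, 2 on parse/usage errors.

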