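test_that("IRIs are minted deterministically with pmcid > doi > pmid fallback", {
  pol <- iri_policy("https://example.org/b")
  meta <- list(pmcid = "PMC2628047", doi = "10.1/x", pmid = "123")
  expect_identical(mint_iri("article", meta, pol),
                   "https://example.org/b/PMC2628047#article")
  expect_identical(mint_iri("article", meta, pol),
                   mint_iri("article", meta, pol))
  expect_identical(mint_iri("record", meta, pol),
                   "https://example.org/b/PMC2628047#record")
  no_pmc <- list(pmcid = NULL, doi = "10.5808/GI.2019.17.2.e14", pmid = "1")
  expect_identical(mint_iri("article", no_pmc, pol),
                   "https://example.org/b/10.5808_GI.2019.17.2.e14#article")
  pmid_only <- list(pmcid = NULL, doi = NULL, pmid = "31307013")
  expect_identical(mint_iri("issue", pmid_only, pol),
                   "https://example.org/b/31307013#issue")
  expect_identical(mint_iri("annotation", meta, pol, annotation_index = 2),
                   "https://example.org/b/PMC2628047#ann-2")
  expect_error(mint_iri("article", list(), pol), "no pmcid, doi or pmid")
  expect_error(mint_iri("annotation", meta, pol), "annotation_index")
})

test_that("iri_policy rejects malformed bases and fragments", {
  expect_error(iri_policy("not-an-iri"), "absolute IRI")
  expect_error(iri_policy("https://x.org/a#frag"), "absolute IRI")
  expect_error(iri_policy("https://x.org", article_fragment = "a#b"), "#")
})

test_that("the isPartOf chain is contiguous for all four volume/issue combinations", {
  for (hv in c(TRUE, FALSE)) {
    for (hi in c(TRUE, FALSE)) {
      doc <- complete_markup(seed = 30 + hv * 2 + hi,
                             has_volume = hv, has_issue = hi)
      want <- c(if (hi) "PublicationIssue", if (hv) "PublicationVolume",
                "Periodical")
      got <- vapply(doc$periodical_chain, function(n) n$type, character(1))
      expect_identical(got, want)
      # walk isPartOf from the article; it must visit every chain node in
      # order and terminate at the Periodical with no gaps
      ref <- doc$article$properties$isPartOf
      for (node in doc$periodical_chain) {
        expect_identical(ref$`@id`, node$id)
        ref <- node$properties$isPartOf
      }
      expect_null(ref)
    }
  }
})

test_that("an article with no journal metadata has no chain and no isPartOf", {
  art <- parse_jats(paste0(
    "<article><front><article-meta>",
    "<article-id pub-id-type=\"pmc\">77</article-id>",
    "<title-group><article-title>T</article-title></title-group>",
    "</article-meta></front></article>"))
  doc <- build_markup(art$metadata, art$periodical)
  expect_length(doc$periodical_chain, 0)
  expect_null(doc$article$properties$isPartOf)
  expect_identical(serialize_jsonld(parse_jsonld(serialize_jsonld(doc))),
                   serialize_jsonld(doc))
})

test_that("about/subjectOf closure holds bidirectionally over randomized fixtures", {
  for (seed in 1:25) {
    n_terms <- seed %% 4
    mult <- if (n_terms == 0) NULL else
      setNames(seq_len(n_terms) %% 3 + 1,
               paste0("http://x.org/t", seq_len(n_terms)))
    doc <- complete_markup(seed = seed, mult = mult,
                           has_volume = seed %% 2 == 0,
                           has_issue = seed %% 3 == 0)
    about <- doc$article$properties$about
    ann_ids <- vapply(doc$annotations, function(a) a$id, character(1))
    if (length(ann_ids) == 0) {
      expect_null(about)
    } else {
      expect_identical(vapply(about, function(r) r$`@id`, character(1)),
                       ann_ids)
    }
    for (a in doc$annotations) {
      expect_identical(a$properties$subjectOf$`@id`, doc$article$id)
    }
  }
})

test_that("annotation nodes carry term IRI, label, hint and occurrence count", {
  doc <- complete_markup(
    seed = 50, mult = c("GO:0008150" = 3, "CHEBI:15377" = 1))
  expect_length(doc$annotations, 2)
  first <- doc$annotations[[1]]
  expect_identical(first$type, "DefinedTerm")
  expect_identical(first$properties$sameAs,
                   "http://purl.obolibrary.org/obo/GO_0008150")
  expect_identical(first$properties$`biotea:occurrences`, 3L)
  expect_identical(first$properties$inDefinedTermSet,
                   "http://purl.obolibrary.org/obo/GO_")
  expect_match(first$id, "#ann-1$")
  expect_match(doc$annotations[[2]]$id, "#ann-2$")
})

test_that("build_markup rejects empty titles and duplicate aggregate terms", {
  art <- parse_jats(make_jats_fixture(seed = 8))
  meta <- art$metadata
  meta$title <- ""
  expect_error(build_markup(meta, art$periodical), "title")
  dup <- tibble::tibble(
    term_iri = c("http://x.org/a", "http://x.org/a"),
    label = c("a", "a"), occurrences = c(2L, 1L),
    first_offset = c(0L, 5L), ontology_hint = NA_character_)
  expect_error(build_markup(art$metadata, art$periodical, dup), "duplicate")
})

test_that("the record node separates structured data from the publication", {
  doc <- complete_markup(seed = 51)
  expect_identical(doc$record$type, "CreativeWork")
  expect_identical(doc$record$properties$mainEntity$`@id`, doc$article$id)
  expect_identical(doc$article$type, "ScholarlyArticle")
})
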