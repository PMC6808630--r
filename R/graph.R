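# Graph builder: assemble article metadata, periodical context and term
# aggregates into the Bioschemas entity graph.
#
# The graph keeps the structured-data record separate from the publication:
# a top-level schema:CreativeWork record node points at the
# schema:ScholarlyArticle via schema:mainEntity. The article sits in a
# containment chain article -> (issue) -> (volume) -> periodical via
# schema:isPartOf, and is linked to its annotations by the reciprocal pair
# schema:about / schema:subjectOf.

BIOTEA_NS <- "https://biotea.github.io/ns#"
OCCURRENCES_PROP <- "biotea:occurrences"

#' IRI minting policy
#'
#' Controls how node IRIs are formed: `{base_iri}/{article-id}#{fragment}`.
#'
#' @param base_iri Absolute IRI, no fragment; a trailing `/` is dropped.
#' @param article_fragment,record_fragment Fragment names for the article
#'   and record nodes.
#' @param annotation_fragment_prefix Prefix for annotation fragments;
#'   annotation *i* gets `#<prefix><i>` (1-based, in aggregate order).
#' @return An `iri_policy` object.
#' @export
iri_policy <- function(base_iri = "https://biotea.github.io/bioschemas",
                       article_fragment = "article",
                       record_fragment = "record",
                       annotation_fragment_prefix = "ann-") {
  if (!is_absolute_iri(base_iri) || grepl("#", base_iri)) {
    stop("`base_iri` must be an absolute IRI without a fragment",
         call. = FALSE)
  }
  frags <- c(article_fragment, record_fragment, annotation_fragment_prefix)
  if (any(grepl("#", frags)) || any(!nzchar(c(article_fragment,
                                              record_fragment)))) {
    stop("fragments must be non-empty and contain no '#'", call. = FALSE)
  }
  structure(
    list(base_iri = sub("/+$", "", base_iri),
         article_fragment = article_fragment,
         record_fragment = record_fragment,
         annotation_fragment_prefix = annotation_fragment_prefix),
    class = "iri_policy"
  )
}

#' Mint a deterministic node IRI
#'
#' The article slug is the first available identifier in the order
#' pmcid > doi (with `/` replaced by `_`) > pmid; minting fails when the
#' metadata carries no identifier at all.
#'
#' @param entity_kind One of `"record"`, `"article"`, `"periodical"`,
#'   `"volume"`, `"issue"`, `"annotation"`.
#' @param meta An `article_metadata` (or any list with `pmcid`, `doi`,
#'   `pmid`).
#' @param policy An [iri_policy()].
#' @param annotation_index 1-based index, required for annotations.
#' @return The IRI as a string; identical inputs always yield identical
#'   IRIs.
#' @examples
#' meta <- list(pmcid = "PMC2628047", doi = NULL, pmid = NULL)
#' mint_iri("article", meta, iri_policy("https://example.org/b"))
#' @export
mint_iri <- function(entity_kind = c("record", "article", "periodical",
                                     "volume", "issue", "annotation"),
                     meta, policy = iri_policy(), annotation_index = NULL) {
  entity_kind <- match.arg(entity_kind)
  stopifnot(inherits(policy, "iri_policy"))
  slug <- if (!is.null(meta$pmcid)) {
    meta$pmcid
  } else if (!is.null(meta$doi)) {
    gsub("/", "_", meta$doi, fixed = TRUE)
  } else if (!is.null(meta$pmid)) {
    meta$pmid
  } else {
    stop("cannot mint an IRI: metadata has no pmcid, doi or pmid",
         call. = FALSE)
  }
  frag <- switch(entity_kind,
    record = policy$record_fragment,
    article = policy$article_fragment,
    periodical = "journal",
    volume = "volume",
    issue = "issue",
    annotation = {
      if (is.null(annotation_index) || annotation_index < 1) {
        stop("`annotation_index` must be >= 1 for annotation IRIs",
             call. = FALSE)
      }
      paste0(policy$annotation_fragment_prefix, as.integer(annotation_index))
    }
  )
  paste0(policy$base_iri, "/", slug, "#", frag)
}

iri_ref <- function(iri) list(`@id` = iri)

is_iri_ref <- function(v) {
  is.list(v) && identical(names(v), "@id")
}

entity_node <- function(id, type, properties = list()) {
  stopifnot(is.character(id), nzchar(id), is.character(type), nzchar(type))
  # drop empty values: absent fields are omitted, never emitted as "" / []
  properties <- properties[!vapply(properties, is_empty_value, logical(1))]
  structure(list(id = id, type = type, properties = properties),
            class = "entity_node")
}

person_node <- function(surname, given_names = NULL, orcid = NULL) {
  p <- list(`@type` = "Person", familyName = surname)
  if (!is.null(given_names) && !is.na(given_names) && nzchar(given_names)) {
    p$givenName <- given_names
    p$name <- paste(given_names, surname)
  } else {
    p$name <- surname
  }
  if (!is.null(orcid) && !is.na(orcid) && nzchar(orcid)) p$sameAs <- orcid
  p
}

citation_node <- function(row) {
  n <- list(`@type` = "CreativeWork")
  if (!is.na(row$title)) n$name <- row$title
  ids <- c(
    if (!is.na(row$doi)) row$doi,
    if (!is.na(row$pmid)) paste0("pmid:", row$pmid)
  )
  if (length(ids) > 0) n$identifier <- as.list(ids)
  n$description <- row$raw_text
  n
}

#' Build the Bioschemas markup document for one article
#'
#' Assembles the full entity graph: the CreativeWork record node, the
#' ScholarlyArticle, the periodical containment chain (only the levels
#' actually present -- a missing volume or issue is omitted and the
#' `isPartOf` chain re-linked contiguously), and one DefinedTerm node per
#' term aggregate. Annotation nodes carry `name`, `sameAs` (the ontology
#' term IRI), `inDefinedTermSet` (when an ontology namespace is known),
#' `subjectOf` (back-link to the article) and the extension property
#' `biotea:occurrences`; the article's `about` lists them in aggregate
#' order, so the about/subjectOf closure holds by construction.
#'
#' @param meta `article_metadata` from [parse_jats()].
#' @param periodical `periodical_context` from [parse_jats()] (may have all
#'   fields `NULL` for an article with no journal metadata).
#' @param aggregates Tibble from [aggregate_terms()] (possibly empty, or
#'   `NULL` for no annotations).
#' @param policy An [iri_policy()].
#' @return A `markup_document`: list with `record`, `article`,
#'   `periodical_chain` (entity nodes, innermost first) and `annotations`.
#' @seealso [serialize_jsonld()], [validate_document()]
#' @export
build_markup <- function(meta, periodical, aggregates = NULL,
                         policy = iri_policy()) {
  if (inherits(meta, "jats_article")) {
    if (missing(periodical) || is.null(periodical)) {
      periodical <- meta$periodical
    }
    meta <- meta$metadata
  }
  if (is_empty_value(meta$title)) {
    stop("cannot build markup: article title is empty", call. = FALSE)
  }
  if (!is.null(aggregates) && nrow(aggregates) > 0 &&
      anyDuplicated(aggregates$term_iri)) {
    stop("duplicate term IRIs among aggregates", call. = FALSE)
  }

  article_id <- mint_iri("article", meta, policy)
  record_id <- mint_iri("record", meta, policy)

  # periodical chain, innermost first; each level isPartOf the next present
  chain <- list()
  periodical_iri <- NULL
  if (!is_empty_value(periodical$journal_name)) {
    periodical_iri <- mint_iri("periodical", meta, policy)
    issns <- c(periodical$issn_print, periodical$issn_electronic)
    props <- list(name = periodical$journal_name)
    if (length(issns) > 0) props$issn <- as.list(issns)
    if (!is_empty_value(periodical$publisher)) {
      props$publisher <- list(`@type` = "Organization",
                              name = periodical$publisher)
    }
    periodical_node <- entity_node(periodical_iri, "Periodical", props)
    volume_iri <- NULL
    volume_node <- NULL
    if (!is_empty_value(periodical$volume)) {
      volume_iri <- mint_iri("volume", meta, policy)
      volume_node <- entity_node(volume_iri, "PublicationVolume", list(
        volumeNumber = periodical$volume,
        isPartOf = iri_ref(periodical_iri)
      ))
    }
    issue_node <- NULL
    if (!is_empty_value(periodical$issue)) {
      issue_node <- entity_node(mint_iri("issue", meta, policy),
                                "PublicationIssue", list(
        issueNumber = periodical$issue,
        isPartOf = iri_ref(volume_iri %||% periodical_iri)
      ))
    }
    chain <- c(list(issue_node), list(volume_node), list(periodical_node))
    chain <- chain[!vapply(chain, is.null, logical(1))]
  }
  article_parent <- if (length(chain) > 0) chain[[1]]$id else NULL

  # annotation nodes, in aggregate order (occurrences desc, IRI asc)
  annotations <- list()
  if (!is.null(aggregates) && nrow(aggregates) > 0) {
    annotations <- lapply(seq_len(nrow(aggregates)), function(i) {
      a <- aggregates[i, ]
      props <- list(
        name = a$label,
        sameAs = a$term_iri,
        subjectOf = iri_ref(article_id)
      )
      if (!is.na(a$ontology_hint)) props$inDefinedTermSet <- a$ontology_hint
      props[[OCCURRENCES_PROP]] <- as.integer(a$occurrences)
      entity_node(mint_iri("annotation", meta, policy, annotation_index = i),
                  "DefinedTerm", props)
    })
  }

  article_props <- list(name = meta$title)
  ids <- c(meta$pmcid, meta$doi, meta$pmid)
  if (length(ids) > 0) article_props$identifier <- as.list(ids)
  if (nrow(meta$authors) > 0) {
    article_props$author <- lapply(seq_len(nrow(meta$authors)), function(i) {
      person_node(meta$authors$surname[[i]], meta$authors$given_names[[i]],
                  meta$authors$orcid[[i]])
    })
  }
  article_props$description <- meta$abstract
  article_props$datePublished <- meta$date_published
  article_props$pageStart <- meta$page_start
  article_props$pageEnd <- meta$page_end
  article_props$license <- meta$license_url
  if (length(meta$keywords) > 0) {
    article_props$keywords <- as.list(meta$keywords)
  }
  if (!is.null(meta$pmcid)) {
    article_props$url <- paste0(
      "https://www.ncbi.nlm.nih.gov/pmc/articles/", meta$pmcid, "/")
  }
  if (!is.null(article_parent)) {
    article_props$isPartOf <- iri_ref(article_parent)
  }
  if (nrow(meta$citations) > 0) {
    article_props$citation <- lapply(
      seq_len(nrow(meta$citations)),
      function(i) citation_node(meta$citations[i, ]))
  }
  if (length(annotations) > 0) {
    article_props$about <- lapply(annotations, function(a) iri_ref(a$id))
  }
  article <- entity_node(article_id, "ScholarlyArticle", article_props)

  record <- entity_node(record_id, "CreativeWork",
                        list(mainEntity = iri_ref(article_id)))

  structure(
    list(record = record, article = article, periodical_chain = chain,
         annotations = annotations),
    class = "markup_document"
  )
}

#' @export
print.markup_document <- function(x, ...) {
  cat("<markup_document> ", x$article$properties$name %||% "(untitled)",
      "\n", sep = "")
  cat("  article: ", x$article$id, "\n", sep = "")
  cat("  chain:   ",
      if (length(x$periodical_chain) == 0) "(none)" else
        paste(vapply(x$periodical_chain, function(n) n$type, character(1)),
              collapse = " -> "),
      "\n  annotations: ", length(x$annotations), "\n", sep = "")
  invisible(x)
}

all_nodes <- function(doc) {
  c(list(doc$record, doc$article), doc$periodical_chain, doc$annotations)
}

# Check the structural contracts every markup document must satisfy.
# Returns a character vector of violated invariants (empty when sound).
document_violations <- function(doc) {
  v <- character(0)
  ids <- vapply(all_nodes(doc), function(n) n$id, character(1))
  if (anyDuplicated(ids)) {
    v <- c(v, "node ids are not unique within the document")
  }
  main <- doc$record$properties$mainEntity
  if (!is_iri_ref(main) || !identical(main$`@id`, doc$article$id)) {
    v <- c(v, "record.mainEntity does not reference the article node")
  }
  # isPartOf chain: article -> chain[1] -> ... -> Periodical, no gaps
  chain <- doc$periodical_chain
  if (length(chain) > 0) {
    expected <- doc$article$properties$isPartOf
    for (node in chain) {
      if (!is_iri_ref(expected) || !identical(expected$`@id`, node$id)) {
        v <- c(v, "isPartOf chain is not contiguous")
        break
      }
      expected <- node$properties$isPartOf
    }
    if (!is.null(chain[[length(chain)]]$properties$isPartOf)) {
      v <- c(v, "Periodical node must terminate the isPartOf chain")
    }
    if (chain[[length(chain)]]$type != "Periodical") {
      v <- c(v, "isPartOf chain does not end at a Periodical")
    }
  } else if (!is.null(doc$article$properties$isPartOf)) {
    v <- c(v, "article has a dangling isPartOf reference")
  }
  # bidirectional about/subjectOf closure
  about <- doc$article$properties$about %||% list()
  about_ids <- vapply(about, function(r) {
    if (is_iri_ref(r)) r$`@id` else NA_character_
  }, character(1))
  ann_ids <- vapply(doc$annotations, function(a) a$id, character(1))
  if (anyNA(about_ids) ||
      !identical(sort_c(about_ids), sort_c(ann_ids))) {
    v <- c(v, "article.about does not match the annotation node set")
  }
  for (a in doc$annotations) {
    so <- a$properties$subjectOf
    if (!is_iri_ref(so) || !identical(so$`@id`, doc$article$id)) {
      v <- c(v, paste0("annotation <", a$id,
                       "> subjectOf does not reference the article"))
    }
  }
  v
}
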