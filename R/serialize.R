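# Deterministic JSON-LD serialization of markup documents, the inverse
# parser for the emitted shape, and byte-preserving HTML embedding.

JSONLD_MEDIA_TYPE <- "application/ld+json"
SCHEMA_ORG_CONTEXT <- "https://schema.org"

node_to_list <- function(node) {
  props <- node$properties
  ord <- sort_c(names(props))
  c(list(`@id` = node$id, `@type` = node$type), props[ord])
}

uses_extension <- function(doc) {
  any(vapply(all_nodes(doc), function(n) {
    any(grepl("^biotea:", names(n$properties)))
  }, logical(1)))
}

#' Serialize a markup document as JSON-LD
#'
#' Emits a single top-level object with an `@context` of
#' `"https://schema.org"` (extended with the `biotea:` namespace when
#' occurrence counts are present) and an `@graph` array holding the record,
#' the article, the periodical chain (innermost first) and the annotation
#' nodes. Within each node, keys are ordered `@id`, `@type`, then
#' properties in byte-wise alphabetical order, so serialization is a pure
#' function of the document: equal inputs yield byte-identical text, and
#' serialize -> parse -> serialize is a fixed point.
#'
#' Documents violating the structural invariants (mainEntity link, isPartOf
#' contiguity, about/subjectOf closure) are refused with the violated
#' invariant named.
#'
#' @param doc A [markup_document].
#' @return JSON-LD text (UTF-8, 2-space indentation, LF line endings, no
#'   trailing newline).
#' @export
serialize_jsonld <- function(doc) {
  stopifnot(inherits(doc, "markup_document"))
  bad <- document_violations(doc)
  if (length(bad) > 0) {
    stop("refusing to serialize an inconsistent document: ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  ctx <- if (uses_extension(doc)) {
    list(SCHEMA_ORG_CONTEXT, list(biotea = BIOTEA_NS))
  } else {
    SCHEMA_ORG_CONTEXT
  }
  graph <- lapply(all_nodes(doc), node_to_list)
  txt <- jsonlite::toJSON(list(`@context` = ctx, `@graph` = graph),
                          auto_unbox = TRUE, pretty = 2, digits = NA)
  gsub("\r\n", "\n", as.character(txt))
}

list_to_node <- function(x) {
  if (is.null(x$`@id`) || is.null(x$`@type`)) {
    stop("graph node without @id/@type", call. = FALSE)
  }
  props <- x[setdiff(names(x), c("@id", "@type"))]
  entity_node(x$`@id`, x$`@type`, props)
}

#' Parse JSON-LD in the emitted shape back into a markup document
#'
#' The inverse of [serialize_jsonld()] for documents this package emits:
#' nodes are recognized by `@type` (CreativeWork record, ScholarlyArticle,
#' the PublicationIssue/PublicationVolume/Periodical chain, DefinedTerm
#' annotations), preserving `@graph` order.
#'
#' @param json_text JSON-LD text, or a path to a file.
#' @return A [markup_document].
#' @export
parse_jsonld <- function(json_text) {
  raw <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON-LD: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!is.list(raw) || is.null(raw$`@graph`)) {
    stop("not a JSON-LD document in the emitted shape (no @graph)",
         call. = FALSE)
  }
  record <- NULL
  article <- NULL
  chain <- list()
  annotations <- list()
  for (x in raw$`@graph`) {
    node <- list_to_node(x)
    if (node$type == "CreativeWork" && is.null(record)) {
      record <- node
    } else if (node$type == "ScholarlyArticle" && is.null(article)) {
      article <- node
    } else if (node$type %in% c("PublicationIssue", "PublicationVolume",
                                "Periodical")) {
      chain <- c(chain, list(node))
    } else if (node$type == "DefinedTerm") {
      annotations <- c(annotations, list(node))
    } else {
      stop("unexpected node type '", node$type, "' in @graph",
           call. = FALSE)
    }
  }
  if (is.null(record) || is.null(article)) {
    stop("JSON-LD document lacks the record or article node", call. = FALSE)
  }
  structure(
    list(record = record, article = article, periodical_chain = chain,
         annotations = annotations),
    class = "markup_document"
  )
}

#' Embed markup into an HTML page
#'
#' Appends a `<script type="application/ld+json">` element containing
#' [serialize_jsonld()] output as the last child of `<body>`; pages without
#' a body element get the script appended at the end of the document. All
#' pre-existing content is byte-preserved (the page is never re-parsed or
#' re-serialized). Machine-readable markup deliberately goes at the end of
#' the page so it never delays user-visible content.
#'
#' @param html_text The HTML page as a string.
#' @param doc A [markup_document].
#' @return The page text with the markup script embedded.
#' @export
embed_in_html <- function(html_text, doc) {
  stopifnot(is.character(html_text), length(html_text) == 1)
  script <- paste0("<script type=\"", JSONLD_MEDIA_TYPE, "\">\n",
                   serialize_jsonld(doc), "\n</script>")
  close_tags <- gregexpr("</body[[:space:]]*>", html_text,
                         ignore.case = TRUE)[[1]]
  if (close_tags[1] == -1) {
    return(paste0(html_text, script, "\n"))
  }
  at <- close_tags[length(close_tags)]  # last </body>
  paste0(substr(html_text, 1, at - 1), script,
         substr(html_text, at, nchar(html_text)))
}

#' Extract embedded JSON-LD markup from an HTML page
#'
#' Pulls the content of the last `application/ld+json` script element, as
#' written by [embed_in_html()].
#'
#' @param html_text The HTML page as a string.
#' @return The JSON-LD text, or `NULL` when no markup script is present.
#' @export
extract_embedded_markup <- function(html_text) {
  m <- gregexpr(
    "(?s)<script type=\"application/ld\\+json\">\n.*?\n</script>",
    html_text, perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  i <- length(m)
  chunk <- substr(html_text, m[i],
                  m[i] + attr(m, "match.length")[i] - 1)
  sub("^<script type=\"application/ld\\+json\">\n", "",
      sub("\n</script>$", "", chunk))
}
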