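# Sitemap generation: expose an article collection to search-engine
# crawlers as a standard sitemaps.org urlset.

SITEMAP_NS <- "http://www.sitemaps.org/schemas/sitemap/0.9"

#' Build a sitemap for a collection of articles
#'
#' One `<url>` entry per article id, in input order, with
#' `loc = "{base_url}?pmc={id}"` by default -- the URL pattern of the
#' showcase pages this markup is served from. Output is deterministic.
#'
#' @param article_ids Character vector of numeric PMC ids (digits only,
#'   duplicates are an error). May be empty.
#' @param base_url Absolute base URL of the article pages.
#' @param lastmod Optional ISO-8601 date applied to every entry.
#' @param url_template Template with `{base}` and `{id}` placeholders, for
#'   deployments using a different URL layout.
#' @return Sitemap XML text.
#' @examples
#' cat(build_sitemap("2628047", "http://biotea.github.io/bioschemas"))
#' @export
build_sitemap <- function(article_ids, base_url,
                          lastmod = NULL,
                          url_template = "{base}?pmc={id}") {
  article_ids <- as.character(article_ids)
  if (!is_absolute_iri(base_url)) {
    stop("`base_url` must be an absolute URL", call. = FALSE)
  }
  if (length(article_ids) > 0) {
    if (any(!grepl("^[0-9]+$", article_ids))) {
      stop("article ids must be non-empty digit strings", call. = FALSE)
    }
    if (anyDuplicated(article_ids)) {
      stop("duplicate article id '",
           article_ids[duplicated(article_ids)][1], "'", call. = FALSE)
    }
  }
  entries <- vapply(article_ids, function(id) {
    loc <- gsub("{id}", id,
                gsub("{base}", base_url, url_template, fixed = TRUE),
                fixed = TRUE)
    paste0(
      "  <url>\n",
      "    <loc>", xml_escape(loc), "</loc>\n",
      if (!is.null(lastmod)) paste0("    <lastmod>", xml_escape(lastmod),
                                    "</lastmod>\n") else "",
      "  </url>\n")
  }, character(1), USE.NAMES = FALSE)
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<urlset xmlns=\"", SITEMAP_NS, "\">\n",
    paste(entries, collapse = ""),
    "</urlset>\n")
}
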