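# JATS reader: parse a JATS XML article record (bare or inside an OAI-PMH
# GetRecord envelope) into article metadata plus its periodical context.
# Elements are matched by local name throughout: PMC-OAI responses vary in
# namespace declarations, so prefixes are never relied on.

#' Canonicalize an article identifier
#'
#' @param raw Non-empty identifier text as found in the wild.
#' @param id_type `"pmc"`, `"doi"` or `"pmid"`.
#' @return The canonical form: `pmc` gains the `PMC` prefix
#'   (`"2628047"` -> `"PMC2628047"`), `doi` is stripped of `doi:` /
#'   `https://doi.org/` prefixes, `pmid` is digits only. Idempotent for all
#'   three types.
#' @examples
#' normalize_identifier("2628047", "pmc")
#' normalize_identifier("https://doi.org/10.5808/GI.2019.17.2.e14", "doi")
#' @export
normalize_identifier <- function(raw, id_type = c("pmc", "doi", "pmid")) {
  id_type <- match.arg(id_type)
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) ||
      !nzchar(trimws(raw))) {
    stop("`raw` must be a non-empty string", call. = FALSE)
  }
  raw <- trimws(raw)
  switch(id_type,
    pmc = {
      bare <- sub("^[Pp][Mm][Cc]", "", raw)
      if (!grepl("^[0-9]+$", bare)) {
        stop("malformed PMC identifier: '", raw, "'", call. = FALSE)
      }
      paste0("PMC", bare)
    },
    doi = {
      doi <- sub("^[Hh][Tt][Tt][Pp][Ss]?://(dx\\.)?doi\\.org/", "", raw)
      doi <- sub("^[Dd][Oo][Ii]:\\s*", "", doi)
      if (!nzchar(doi)) stop("malformed DOI: '", raw, "'", call. = FALSE)
      doi
    },
    pmid = {
      pmid <- sub("^[Pp][Mm][Ii][Dd]:\\s*", "", raw)
      if (!grepl("^[0-9]+$", pmid)) {
        stop("malformed PMID (digits expected): '", raw, "'", call. = FALSE)
      }
      pmid
    }
  )
}

# xml_find_* with local-name matching, relative to `node`.
ln_all <- function(node, name) {
  xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))
}
ln_first <- function(node, name) {
  xml2::xml_find_first(node, paste0(".//*[local-name()='", name, "']"))
}
ln_text <- function(node, name) {
  hit <- ln_first(node, name)
  if (inherits(hit, "xml_missing")) return(NULL)
  out <- squish(xml2::xml_text(hit))
  if (nzchar(out)) out else NULL
}

# Attribute lookup ignoring namespace prefix (xlink:href arrives as "href"
# with xml2 once the namespace is unknown, but not always; check both).
attr_any <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) {
    attrs <- xml2::xml_attrs(node)
    hit <- grepl(paste0("(^|:)", name, "$"), names(attrs))
    v <- if (any(hit)) attrs[[which(hit)[1]]] else NA_character_
  }
  v
}

parse_pub_date <- function(article_meta) {
  dates <- xml2::xml_find_all(
    article_meta, "./*[local-name()='pub-date']")
  if (length(dates) == 0) return(NULL)
  type_of <- function(d) {
    t <- xml2::xml_attr(d, "pub-type")
    if (is.na(t)) t <- xml2::xml_attr(d, "date-type")
    if (is.na(t)) "" else t
  }
  types <- vapply(dates, type_of, character(1))
  pick <- which(types == "epub")[1]
  if (is.na(pick)) pick <- which(types == "ppub")[1]
  if (is.na(pick)) pick <- 1L
  d <- dates[[pick]]
  year <- ln_text(d, "year")
  if (is.null(year)) return(NULL)
  month <- ln_text(d, "month")
  day <- ln_text(d, "day")
  pad2 <- function(x) formatC(as.integer(x), width = 2, flag = "0")
  # Serialize at the real precision present in the record; a year-only
  # pub-date stays "2019", never a fabricated "2019-01-01".
  if (is.null(month)) return(year)
  if (is.null(day)) return(paste0(year, "-", pad2(month)))
  paste0(year, "-", pad2(month), "-", pad2(day))
}

parse_contributors <- function(article_meta, article) {
  groups <- xml2::xml_find_all(
    article_meta, "./*[local-name()='contrib-group']")
  contribs <- xml2::xml_find_all(
    groups, "./*[local-name()='contrib']")
  keep <- vapply(contribs, function(c) {
    t <- xml2::xml_attr(c, "contrib-type")
    is.na(t) || t == "author"
  }, logical(1))
  contribs <- contribs[keep]
  # Affiliations referenced by id from anywhere in the front matter.
  aff_nodes <- ln_all(article, "aff")
  aff_by_id <- list()
  for (a in aff_nodes) {
    id <- xml2::xml_attr(a, "id")
    label <- xml2::xml_find_first(a, "./*[local-name()='label']")
    txt <- squish(xml2::xml_text(a))
    if (!inherits(label, "xml_missing")) {
      lab <- squish(xml2::xml_text(label))
      txt <- squish(sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", lab)),
                        "", txt))
    }
    if (!is.na(id)) aff_by_id[[id]] <- txt
  }
  rows <- lapply(contribs, function(c) {
    name_el <- xml2::xml_find_first(c, "./*[local-name()='name']")
    collab <- xml2::xml_find_first(c, "./*[local-name()='collab']")
    if (!inherits(name_el, "xml_missing")) {
      surname <- ln_text(name_el, "surname") %||% ""
      given <- ln_text(name_el, "given-names")
    } else if (!inherits(collab, "xml_missing")) {
      surname <- squish(xml2::xml_text(collab))
      given <- NULL
    } else {
      surname <- squish(xml2::xml_text(c))
      given <- NULL
    }
    orcid <- NULL
    for (cid in xml2::xml_find_all(c, "./*[local-name()='contrib-id']")) {
      if (identical(xml2::xml_attr(cid, "contrib-id-type"), "orcid")) {
        orcid <- squish(xml2::xml_text(cid))
      }
    }
    affs <- character(0)
    for (a in xml2::xml_find_all(c, "./*[local-name()='aff']")) {
      affs <- c(affs, squish(xml2::xml_text(a)))
    }
    for (x in xml2::xml_find_all(c, "./*[local-name()='xref']")) {
      if (identical(xml2::xml_attr(x, "ref-type"), "aff")) {
        rid <- xml2::xml_attr(x, "rid")
        if (!is.na(rid) && !is.null(aff_by_id[[rid]])) {
          affs <- c(affs, aff_by_id[[rid]])
        }
      }
    }
    tibble::tibble(
      surname = surname,
      given_names = given %||% NA_character_,
      orcid = orcid %||% NA_character_,
      affiliations = list(affs)
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(surname = character(), given_names = character(),
                          orcid = character(), affiliations = list()))
  }
  dplyr::bind_rows(rows)
}

parse_citations <- function(article) {
  refs <- xml2::xml_find_all(
    article, ".//*[local-name()='ref-list']/*[local-name()='ref']")
  if (length(refs) == 0) {
    return(tibble::tibble(label = character(), title = character(),
                          doi = character(), pmid = character(),
                          raw_text = character()))
  }
  dplyr::bind_rows(lapply(refs, function(r) {
    doi <- pmid <- NA_character_
    for (p in ln_all(r, "pub-id")) {
      t <- xml2::xml_attr(p, "pub-id-type")
      v <- squish(xml2::xml_text(p))
      if (identical(t, "doi")) doi <- normalize_identifier(v, "doi")
      if (identical(t, "pmid")) pmid <- v
    }
    tibble::tibble(
      label = ln_text(r, "label") %||% NA_character_,
      title = ln_text(r, "article-title") %||% NA_character_,
      doi = doi,
      pmid = pmid,
      raw_text = squish(xml2::xml_text(r))
    )
  }))
}

parse_abstract <- function(article_meta) {
  abstracts <- xml2::xml_find_all(
    article_meta, "./*[local-name()='abstract']")
  if (length(abstracts) == 0) return(NULL)
  ab <- abstracts[[1]]  # first abstract only; trans-abstracts are separate
  ps <- ln_all(ab, "p")
  txt <- if (length(ps) > 0) {
    paste(vapply(ps, function(p) squish(xml2::xml_text(p)), character(1)),
          collapse = "\n\n")
  } else {
    squish(xml2::xml_text(ab))
  }
  if (nzchar(txt)) txt else NULL
}

#' Parse a JATS article record
#'
#' Accepts a bare JATS `<article>` document or one wrapped in an OAI-PMH
#' `GetRecord` envelope (the form returned by the PMC open-access OAI
#' interface); both yield identical results. Absent elements yield absent
#' (`NULL`/`NA`) fields, never placeholder text.
#'
#' @param xml_text JATS XML as a string, or a path to an XML file.
#' @return A `jats_article` object: list with
#'   * `metadata` (`article_metadata`): `title`, `pmcid`, `doi`, `pmid`,
#'     `authors` (tibble in document order: `surname`, `given_names`,
#'     `orcid`, `affiliations`), `abstract`, `keywords`, `license_url`,
#'     `date_published` (ISO 8601 at the record's real precision),
#'     `page_start`, `page_end`, `citations` (tibble: `label`, `title`,
#'     `doi`, `pmid`, `raw_text`);
#'   * `periodical` (`periodical_context`): `journal_name`, `issn_print`,
#'     `issn_electronic`, `publisher`, `volume`, `issue`.
#' @examples
#' art <- parse_jats(make_jats_fixture(seed = 1))
#' art$metadata$title
#' art$periodical$journal_name
#' @export
parse_jats <- function(xml_text) {
  doc <- tryCatch(
    xml2::read_xml(xml_text),
    error = function(e) stop("malformed XML: ", conditionMessage(e),
                             call. = FALSE)
  )
  articles <- xml2::xml_find_all(doc, "//*[local-name()='article']")
  if (length(articles) != 1) {
    stop("expected exactly one <article> element, found ",
         length(articles), call. = FALSE)
  }
  article <- articles[[1]]
  article_meta <- ln_first(article, "article-meta")
  journal_meta <- ln_first(article, "journal-meta")
  if (inherits(article_meta, "xml_missing")) {
    stop("JATS record has no <article-meta> element", call. = FALSE)
  }

  title <- NULL
  tg <- ln_first(article_meta, "title-group")
  if (!inherits(tg, "xml_missing")) title <- ln_text(tg, "article-title")
  title <- title %||% ln_text(article_meta, "article-title")
  if (is.null(title)) {
    stop("JATS record has no non-empty <article-title>", call. = FALSE)
  }

  ids <- list(pmcid = NULL, doi = NULL, pmid = NULL)
  for (idn in xml2::xml_find_all(
    article_meta, "./*[local-name()='article-id']")) {
    t <- xml2::xml_attr(idn, "pub-id-type")
    v <- squish(xml2::xml_text(idn))
    if (!nzchar(v) || is.na(t)) next
    if (t %in% c("pmc", "pmcid")) ids$pmcid <- normalize_identifier(v, "pmc")
    if (t == "doi") ids$doi <- normalize_identifier(v, "doi")
    if (t == "pmid") ids$pmid <- normalize_identifier(v, "pmid")
  }

  keywords <- character(0)
  for (k in xml2::xml_find_all(
    article_meta,
    "./*[local-name()='kwd-group']/*[local-name()='kwd']")) {
    kw <- squish(xml2::xml_text(k))
    if (nzchar(kw)) keywords <- c(keywords, kw)
  }

  license_url <- NULL
  lic <- ln_first(article_meta, "license")
  if (!inherits(lic, "xml_missing")) {
    href <- attr_any(lic, "href")
    if (!is.na(href) && nzchar(href)) license_url <- href
  }

  metadata <- structure(
    list(
      title = title,
      pmcid = ids$pmcid,
      doi = ids$doi,
      pmid = ids$pmid,
      authors = parse_contributors(article_meta, article),
      abstract = parse_abstract(article_meta),
      keywords = keywords,
      license_url = license_url,
      date_published = parse_pub_date(article_meta),
      page_start = ln_text(article_meta, "fpage"),
      page_end = ln_text(article_meta, "lpage"),
      citations = parse_citations(article)
    ),
    class = "article_metadata"
  )

  periodical <- structure(
    list(journal_name = NULL, issn_print = NULL, issn_electronic = NULL,
         publisher = NULL, volume = NULL, issue = NULL),
    class = "periodical_context"
  )
  if (!inherits(journal_meta, "xml_missing")) {
    periodical$journal_name <- ln_text(journal_meta, "journal-title")
    for (issn in xml2::xml_find_all(
      journal_meta, ".//*[local-name()='issn']")) {
      t <- xml2::xml_attr(issn, "pub-type")
      if (is.na(t)) t <- xml2::xml_attr(issn, "publication-format")
      v <- squish(xml2::xml_text(issn))
      if (!nzchar(v)) next
      if (identical(t, "epub") || identical(t, "electronic")) {
        periodical$issn_electronic <- v
      } else {
        periodical$issn_print <- periodical$issn_print %||% v
      }
    }
    periodical$publisher <- ln_text(journal_meta, "publisher-name")
    if (is.null(periodical$journal_name)) {
      stop("JATS <journal-meta> present but no non-empty <journal-title>",
           call. = FALSE)
    }
  }
  periodical$volume <- ln_text(article_meta, "volume")
  periodical$issue <- ln_text(article_meta, "issue")

  structure(list(metadata = metadata, periodical = periodical),
            class = "jats_article")
}

#' @export
print.jats_article <- function(x, ...) {
  m <- x$metadata
  cat("<jats_article> ", m$title, "\n", sep = "")
  cat("  ids: ", paste(c(m$pmcid, m$doi, m$pmid), collapse = " | "),
      "\n", sep = "")
  cat("  authors: ", nrow(m$authors),
      "; citations: ", nrow(m$citations), "\n", sep = "")
  if (!is.null(x$periodical$journal_name)) {
    cat("  journal: ", x$periodical$journal_name,
        if (!is.null(x$periodical$volume))
          paste0(" vol. ", x$periodical$volume),
        if (!is.null(x$periodical$issue))
          paste0(" issue ", x$periodical$issue), "\n", sep = "")
  }
  invisible(x)
}
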