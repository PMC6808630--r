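# Synthetic input generators: deterministic JATS and PubAnnotation
# documents so the whole pipeline builds and tests offline. Content is
# lorem-style ASCII to keep character-offset arithmetic trivial; the
# generators emit exactly the dialects the readers consume, and the same
# seed + parameters always yield byte-identical output.

lorem_pool <- c(
  "lorem", "ipsum", "dolor", "sit", "amet", "consectetur", "adipiscing",
  "elit", "sed", "do", "eiusmod", "tempor", "incididunt", "ut", "labore",
  "et", "dolore", "magna", "aliqua", "enim", "ad", "minim", "veniam",
  "quis", "nostrud", "exercitation", "ullamco", "laboris", "nisi",
  "aliquip", "ex", "ea", "commodo", "consequat"
)

surname_pool <- c(
  "Garcia", "Kim", "Okafor", "Novak", "Silva", "Tanaka", "Muller",
  "Rossi", "Haddad", "Larsen", "Ivanova", "Chen", "Dubois", "Moreau"
)

given_pool <- c(
  "Ana", "Bo", "Carla", "Deniz", "Elena", "Farid", "Grete", "Hiro",
  "Ines", "Jonas", "Keiko", "Lars", "Mira", "Noor"
)

rand_words <- function(n) sample(lorem_pool, n, replace = TRUE)

rand_title <- function() {
  w <- rand_words(sample(4:7, 1))
  w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, nchar(w[1])))
  paste(w, collapse = " ")
}

rand_sentence <- function() {
  w <- rand_words(sample(8:14, 1))
  w[1] <- paste0(toupper(substr(w[1], 1, 1)), substr(w[1], 2, nchar(w[1])))
  paste0(paste(w, collapse = " "), ".")
}

#' Generate a synthetic JATS article record
#'
#' Emits a well-formed JATS XML article honoring every parameter, suitable
#' for [parse_jats()]; with `include_oai_envelope = TRUE` the article is
#' wrapped in an OAI-PMH `GetRecord` envelope as returned by the PMC
#' open-access interface. Same seed and parameters give byte-identical
#' output. The generated corpus is deliberately simple (ASCII lorem text,
#' pool-drawn names); it exercises structure, not linguistic realism.
#'
#' @param seed Integer seed driving all generated content.
#' @param title Article title; generated from the seed when `NULL`.
#' @param n_authors Number of contributor elements (>= 0).
#' @param has_volume,has_issue Include the volume / issue element.
#' @param n_citations Number of `<ref>` elements (>= 0).
#' @param pmcid_digits Digits of the PMC identifier (string).
#' @param include_oai_envelope Wrap in an OAI-PMH GetRecord envelope.
#' @param has_abstract,has_license,has_doi,has_pmid,n_keywords Optional
#'   metadata toggles.
#' @return JATS XML text.
#' @examples
#' art <- parse_jats(make_jats_fixture(seed = 7, n_authors = 3))
#' nrow(art$metadata$authors)
#' @export
make_jats_fixture <- function(seed = 1, title = NULL, n_authors = 2,
                              has_volume = TRUE, has_issue = TRUE,
                              n_citations = 2, pmcid_digits = "2628047",
                              include_oai_envelope = FALSE,
                              has_abstract = TRUE, has_license = TRUE,
                              has_doi = TRUE, has_pmid = TRUE,
                              n_keywords = 3) {
  if (!grepl("^[0-9]+$", pmcid_digits)) {
    stop("`pmcid_digits` must be all digits", call. = FALSE)
  }
  if (n_authors < 0 || n_citations < 0 || n_keywords < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  with_local_seed(seed, {
    title <- title %||% rand_title()
    jw <- rand_words(1)
    journal <- paste("Journal of",
                     paste0(toupper(substr(jw, 1, 1)), substr(jw, 2, 20)),
                     "Research")
    volume <- as.character(sample(1:60, 1))
    issue <- as.character(sample(1:12, 1))
    fpage <- sample(1:400, 1)
    lpage <- fpage + sample(1:15, 1)
    year <- sample(2005:2019, 1)
    month <- sample(1:12, 1)
    day <- sample(1:28, 1)
    doi <- sprintf("10.%d/synth.%s.%d", sample(1000:9999, 1),
                   pmcid_digits, sample(1:99, 1))
    pmid <- paste0(sample(1:9, 1),
                   paste(sample(0:9, 6, replace = TRUE), collapse = ""))

    authors <- character(0)
    if (n_authors > 0) {
      sn <- sample(surname_pool, n_authors, replace = n_authors > length(surname_pool))
      gn <- sample(given_pool, n_authors, replace = n_authors > length(given_pool))
      authors <- vapply(seq_len(n_authors), function(i) {
        orcid <- if (i == 1) {
          sprintf("      <contrib-id contrib-id-type=\"orcid\">https://orcid.org/0000-0002-%04d-%04d</contrib-id>\n",
                  sample(0:9999, 1), sample(0:9999, 1))
        } else ""
        paste0(
          "     <contrib contrib-type=\"author\">\n", orcid,
          "      <name><surname>", xml_escape(sn[i]),
          "</surname><given-names>", xml_escape(gn[i]),
          "</given-names></name>\n",
          "      <xref ref-type=\"aff\" rid=\"aff1\"/>\n",
          "     </contrib>\n")
      }, character(1))
    }

    citations <- character(0)
    if (n_citations > 0) {
      citations <- vapply(seq_len(n_citations), function(i) {
        ct <- rand_title()
        paste0(
          "    <ref id=\"ref", i, "\"><label>", i, "</label>\n",
          "     <element-citation publication-type=\"journal\">\n",
          "      <article-title>", xml_escape(ct), "</article-title>\n",
          "      <year>", sample(1990:2018, 1), "</year>\n",
          "      <pub-id pub-id-type=\"doi\">10.9999/ref.", i,
          ".", sample(100:999, 1), "</pub-id>\n",
          "     </element-citation>\n",
          "    </ref>\n")
      }, character(1))
    }

    keywords <- if (n_keywords > 0) {
      paste0("    <kwd-group>\n",
             paste0("     <kwd>", rand_words(n_keywords), "</kwd>\n",
                    collapse = ""),
             "    </kwd-group>\n")
    } else ""

    abstract <- if (has_abstract) {
      paste0("    <abstract>\n",
             "     <p>", rand_sentence(), " ", rand_sentence(), "</p>\n",
             "     <p>", rand_sentence(), "</p>\n",
             "    </abstract>\n")
    } else ""

    license <- if (has_license) {
      paste0("    <permissions>\n",
             "     <license xmlns:xlink=\"http://www.w3.org/1999/xlink\"",
             " xlink:href=\"https://creativecommons.org/licenses/by/4.0/\">\n",
             "      <license-p>Open access.</license-p>\n",
             "     </license>\n",
             "    </permissions>\n")
    } else ""

    article <- paste0(
      "<article xmlns:xlink=\"http://www.w3.org/1999/xlink\"",
      " article-type=\"research-article\">\n",
      " <front>\n",
      "  <journal-meta>\n",
      "   <journal-title-group><journal-title>", xml_escape(journal),
      "</journal-title></journal-title-group>\n",
      "   <issn pub-type=\"ppub\">", sprintf("%04d-%04d", sample(1000:9999, 1),
                                             sample(1000:9999, 1)), "</issn>\n",
      "   <issn pub-type=\"epub\">", sprintf("%04d-%04d", sample(1000:9999, 1),
                                             sample(1000:9999, 1)), "</issn>\n",
      "   <publisher><publisher-name>Synthetic Science Press",
      "</publisher-name></publisher>\n",
      "  </journal-meta>\n",
      "  <article-meta>\n",
      "   <article-id pub-id-type=\"pmc\">", pmcid_digits, "</article-id>\n",
      if (has_doi) paste0("   <article-id pub-id-type=\"doi\">", doi,
                          "</article-id>\n") else "",
      if (has_pmid) paste0("   <article-id pub-id-type=\"pmid\">", pmid,
                           "</article-id>\n") else "",
      "   <title-group><article-title>", xml_escape(title),
      "</article-title></title-group>\n",
      "   <contrib-group>\n", paste(authors, collapse = ""),
      "   </contrib-group>\n",
      "   <aff id=\"aff1\">Institute of Synthetic Studies</aff>\n",
      "   <pub-date pub-type=\"epub\"><day>", day, "</day><month>", month,
      "</month><year>", year, "</year></pub-date>\n",
      "   <pub-date pub-type=\"ppub\"><year>", year, "</year></pub-date>\n",
      if (has_volume) paste0("   <volume>", volume, "</volume>\n") else "",
      if (has_issue) paste0("   <issue>", issue, "</issue>\n") else "",
      "   <fpage>", fpage, "</fpage>\n",
      "   <lpage>", lpage, "</lpage>\n",
      license, abstract, keywords,
      "  </article-meta>\n",
      " </front>\n",
      " <back>\n",
      "  <ref-list>\n", paste(citations, collapse = ""),
      "  </ref-list>\n",
      " </back>\n",
      "</article>")

    if (include_oai_envelope) {
      paste0(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
        "<OAI-PMH xmlns=\"http://www.openarchives.org/OAI/2.0/\">\n",
        " <responseDate>", year, "-01-01T00:00:00Z</responseDate>\n",
        " <request verb=\"GetRecord\" metadataPrefix=\"pmc\">",
        "https://www.ncbi.nlm.nih.gov/pmc/oai/oai.cgi</request>\n",
        " <GetRecord>\n",
        "  <record>\n",
        "   <header><identifier>oai:pubmedcentral.nih.gov:", pmcid_digits,
        "</identifier></header>\n",
        "   <metadata>\n", article, "\n   </metadata>\n",
        "  </record>\n",
        " </GetRecord>\n",
        "</OAI-PMH>")
    } else {
      paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n", article)
    }
  })
}

#' Generate a synthetic PubAnnotation document
#'
#' Lays out lorem text of (at most) `text_length` characters and places one
#' denotation per requested term occurrence on alternating words, so spans
#' are non-overlapping, in-bounds and strictly increasing. Denotations
#' cycle round-robin through the terms until every requested multiplicity
#' is exhausted; the emitted denotation counts equal `term_multiplicities`
#' exactly. Offsets are 0-based, end-exclusive, counted in characters.
#'
#' @param seed Integer seed.
#' @param text_length Target text capacity in characters.
#' @param term_multiplicities Named positive integer vector: term (IRI or
#'   CURIE) -> number of denotations to place.
#' @param sourceid PubAnnotation source document id (digits, as for a PMC
#'   article).
#' @return PubAnnotation JSON text (fields `text`, `sourcedb`, `sourceid`,
#'   `project`, `denotations`); byte-identical per seed + parameters.
#' @examples
#' make_pubannotation_fixture(seed = 1,
#'   term_multiplicities = c("GO:0008150" = 2, "CHEBI:15377" = 1))
#' @export
make_pubannotation_fixture <- function(seed = 1, text_length = 400,
                                       term_multiplicities = integer(0),
                                       sourceid = "2628047") {
  if (length(term_multiplicities) > 0 &&
      (is.null(names(term_multiplicities)) ||
       any(!nzchar(names(term_multiplicities))) ||
       any(term_multiplicities < 1))) {
    stop("`term_multiplicities` must be a named vector of positive counts",
         call. = FALSE)
  }
  with_local_seed(seed, {
    # fill the text budget with words
    words <- character(0)
    len <- 0L
    repeat {
      w <- rand_words(1)
      extra <- nchar(w) + (if (len > 0) 1L else 0L)
      if (len + extra > text_length) break
      words <- c(words, w)
      len <- len + extra
    }
    text <- paste(words, collapse = " ")

    n_total <- sum(term_multiplicities)
    # denotation k lands on word 2k-1: alternating words keep spans
    # disjoint and strictly increasing
    if (n_total > 0 && (2 * n_total - 1) > length(words)) {
      stop("infeasible packing: ", n_total, " denotations need at least ",
           2 * n_total - 1, " words but the text holds ", length(words),
           call. = FALSE)
    }
    starts <- c(0L, cumsum(nchar(words) + 1L))[seq_along(words)]
    term_seq <- character(0)
    if (n_total > 0) {
      remaining <- term_multiplicities
      while (sum(remaining) > 0) {
        for (t in names(term_multiplicities)) {
          if (remaining[[t]] > 0) {
            term_seq <- c(term_seq, t)
            remaining[[t]] <- remaining[[t]] - 1L
          }
        }
      }
    }
    denotations <- lapply(seq_along(term_seq), function(k) {
      wi <- 2L * k - 1L
      list(id = paste0("T", k),
           span = list(begin = starts[wi],
                       end = starts[wi] + nchar(words[wi])),
           obj = term_seq[[k]])
    })
    payload <- list(
      text = text,
      sourcedb = "PMC",
      sourceid = sourceid,
      project = "synthetic-fixture",
      denotations = denotations
    )
    txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = 2,
                            digits = NA)
    gsub("\r\n", "\n", as.character(txt))
  })
}
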