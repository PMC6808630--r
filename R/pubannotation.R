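# PubAnnotation reader: load denotation-level annotations and aggregate
# them into per-term occurrence counts. Annotations are read from frozen
# files by design -- live annotator services re-annotate against whatever
# ontology version is current, so the same article can yield different
# annotation sets at different times.

#' Default CURIE prefix map
#'
#' Prefixes commonly seen in biomedical annotation projects, mapping to OBO
#' PURL (and MeSH) namespaces. Used by [expand_term()] and
#' [aggregate_terms()]; pass your own named character vector to override or
#' extend.
#'
#' @return Named character vector, prefix -> IRI base.
#' @export
default_prefix_map <- function() {
  c(
    GO = "http://purl.obolibrary.org/obo/GO_",
    CHEBI = "http://purl.obolibrary.org/obo/CHEBI_",
    DOID = "http://purl.obolibrary.org/obo/DOID_",
    HP = "http://purl.obolibrary.org/obo/HP_",
    PR = "http://purl.obolibrary.org/obo/PR_",
    SO = "http://purl.obolibrary.org/obo/SO_",
    NCBITaxon = "http://purl.obolibrary.org/obo/NCBITaxon_",
    MESH = "http://id.nlm.nih.gov/mesh/"
  )
}

#' Parse a PubAnnotation JSON document
#'
#' Character offsets follow PubAnnotation's native convention: 0-based,
#' end-exclusive, counted in characters. No conversion is ever applied.
#' When the document carries its `text`, every span is validated against
#' its bounds.
#'
#' @param json_text PubAnnotation JSON as a string, or a path to a file.
#' @return An `annotation_set`: list with `source_db`, `source_id`,
#'   `project`, `text` (may be `NULL`), and `denotations`, a tibble in
#'   document order with columns `id`, `begin`, `end`, `term`.
#' @examples
#' set <- parse_pubannotation(make_pubannotation_fixture(
#'   seed = 1, term_multiplicities = c("GO:0008150" = 2)))
#' set$denotations
#' @export
parse_pubannotation <- function(json_text) {
  raw <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) stop("malformed PubAnnotation JSON: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(raw)) {
    stop("malformed PubAnnotation JSON: top level must be an object",
         call. = FALSE)
  }
  text <- raw$text
  dens <- raw$denotations %||% list()
  rows <- lapply(seq_along(dens), function(i) {
    d <- dens[[i]]
    id <- d$id %||% paste0("T", i)
    span <- d$span
    if (is.null(span) || is.null(span$begin) || is.null(span$end)) {
      stop("denotation '", id, "' has no span with begin/end", call. = FALSE)
    }
    begin <- as.integer(span$begin)
    end <- as.integer(span$end)
    if (is.na(begin) || is.na(end) || begin < 0 || begin >= end) {
      stop("invalid span for denotation '", id, "': begin=",
           span$begin, ", end=", span$end,
           " (need 0 <= begin < end)", call. = FALSE)
    }
    if (!is.null(text) && end > nchar(text)) {
      stop("span of denotation '", id, "' ends at ", end,
           ", beyond the document text (length ", nchar(text), ")",
           call. = FALSE)
    }
    term <- d$obj
    if (is.null(term) || !nzchar(term)) {
      stop("denotation '", id, "' has an empty term (obj)", call. = FALSE)
    }
    tibble::tibble(id = as.character(id), begin = begin, end = end,
                   term = as.character(term))
  })
  denotations <- if (length(rows) == 0) {
    tibble::tibble(id = character(), begin = integer(), end = integer(),
                   term = character())
  } else {
    dplyr::bind_rows(rows)
  }
  if (anyDuplicated(denotations$id)) {
    dup <- denotations$id[duplicated(denotations$id)][1]
    stop("duplicate denotation id '", dup, "'", call. = FALSE)
  }
  structure(
    list(
      source_db = raw$sourcedb %||% NA_character_,
      source_id = as.character(raw$sourceid %||% NA_character_),
      project = raw$project %||% NULL,
      text = text,
      denotations = denotations
    ),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", x$source_db, ":", x$source_id, " -- ",
      nrow(x$denotations), " denotation(s)\n", sep = "")
  invisible(x)
}

#' Expand a term identifier to an absolute IRI
#'
#' Absolute IRIs pass through unchanged. CURIEs with a known prefix expand
#' against the prefix map; unknown prefixes pass through verbatim with a
#' warning.
#'
#' @param term Character vector of IRIs and/or CURIEs (`prefix:local`).
#' @param prefix_map Named character vector, prefix -> IRI base.
#' @return Character vector of the same length.
#' @examples
#' expand_term("GO:0008150")
#' expand_term("http://example.org/T1")
#' @export
expand_term <- function(term, prefix_map = default_prefix_map()) {
  stopifnot(is.character(term))
  if (any(!nzchar(term) | is.na(term))) {
    stop("empty term cannot be expanded", call. = FALSE)
  }
  vapply(term, function(t) {
    if (is_absolute_iri(t)) return(t)
    m <- regmatches(t, regexec("^([A-Za-z_][A-Za-z0-9_.-]*):(.+)$", t))[[1]]
    if (length(m) == 3) {
      base <- if (m[2] %in% names(prefix_map)) prefix_map[[m[2]]]
      if (!is.null(base)) return(paste0(base, m[3]))
      warning("unknown CURIE prefix '", m[2], "'; term '", t,
              "' passed through verbatim", call. = FALSE)
    }
    t
  }, character(1), USE.NAMES = FALSE)
}

iri_local_name <- function(iri) {
  sub(".*[/#_]", "", iri)
}

iri_namespace <- function(iri) {
  ifelse(grepl("[/#_]", iri), sub("(.*[/#_]).*", "\\1", iri), NA_character_)
}

#' Aggregate denotations into per-term occurrence counts
#'
#' Produces one aggregate per distinct expanded term IRI -- two spans of the
#' same term merge even when their surface text differs, matching the
#' per-term cloud-of-words view of annotated articles. Labels come from the
#' optional label map, falling back to the IRI's local name (the text after
#' the last `/`, `#` or `_`).
#'
#' @param set An `annotation_set` from [parse_pubannotation()].
#' @param labels Optional label map: a named character vector
#'   (IRI -> label) or a two-column data frame (IRI, label), e.g. from
#'   [read_label_map()].
#' @param prefix_map Passed to [expand_term()].
#' @return A tibble with one row per distinct term, columns `term_iri`,
#'   `label`, `occurrences`, `first_offset` (begin of the earliest span),
#'   `ontology_hint` (IRI namespace, `NA` when underivable); ordered by
#'   `occurrences` descending, ties by `term_iri` ascending. The sum of
#'   `occurrences` always equals the number of denotations.
#' @examples
#' set <- parse_pubannotation(make_pubannotation_fixture(
#'   seed = 1, term_multiplicities = c("GO:0008150" = 3, "CHEBI:15377" = 1)))
#' aggregate_terms(set)
#' @export
aggregate_terms <- function(set, labels = NULL,
                            prefix_map = default_prefix_map()) {
  stopifnot(inherits(set, "annotation_set"))
  den <- set$denotations
  if (nrow(den) == 0) {
    return(tibble::tibble(term_iri = character(), label = character(),
                          occurrences = integer(), first_offset = integer(),
                          ontology_hint = character()))
  }
  label_map <- labels
  if (is.data.frame(labels)) {
    label_map <- stats::setNames(as.character(labels[[2]]),
                                 as.character(labels[[1]]))
  }
  den$term_iri <- expand_term(den$term, prefix_map)
  agg <- den |>
    dplyr::group_by(.data$term_iri) |>
    dplyr::summarise(occurrences = dplyr::n(),
                     first_offset = min(.data$begin),
                     .groups = "drop")
  lbl <- iri_local_name(agg$term_iri)
  if (!is.null(label_map)) {
    hit <- unname(label_map[agg$term_iri])
    lbl <- ifelse(is.na(hit), lbl, hit)
  }
  agg$label <- lbl
  agg$ontology_hint <- iri_namespace(agg$term_iri)
  agg <- agg[order(-agg$occurrences, rank_c(agg$term_iri)), ]
  tibble::as_tibble(agg[, c("term_iri", "label", "occurrences",
                            "first_offset", "ontology_hint")])
}

# byte-wise (locale-independent) rank for tie-breaking
rank_c <- function(x) match(x, sort_c(x))

#' Filter term aggregates by occurrence count
#'
#' Keeps terms seen at least `min_occurrences` times; order and counts are
#' preserved. `min_occurrences = 2` corresponds to the "more than one
#' occurrence" view used when rendering annotation clouds.
#'
#' @param aggregates Tibble from [aggregate_terms()].
#' @param min_occurrences Positive integer threshold; 1 keeps everything.
#' @return The filtered tibble.
#' @examples
#' set <- parse_pubannotation(make_pubannotation_fixture(
#'   seed = 1, term_multiplicities = c("GO:0008150" = 3, "CHEBI:15377" = 1)))
#' aggregate_terms(set) |> filter_by_occurrence(2)
#' @export
filter_by_occurrence <- function(aggregates, min_occurrences = 1) {
  if (!is.numeric(min_occurrences) || length(min_occurrences) != 1 ||
      is.na(min_occurrences) || min_occurrences < 1) {
    stop("`min_occurrences` must be a positive integer", call. = FALSE)
  }
  dplyr::filter(aggregates, .data$occurrences >= min_occurrences)
}

#' Read a term-label map from a two-column TSV
#'
#' @param path TSV file with columns: term IRI, preferred label. No header.
#' @return Named character vector (IRI -> label).
#' @export
read_label_map <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) {
    stop("label map must have two tab-separated columns (IRI, label)",
         call. = FALSE)
  }
  stats::setNames(tab[[2]], tab[[1]])
}
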