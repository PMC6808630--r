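# High-level wiring: readers -> aggregation -> graph builder -> serializer
# -> validator. These are the functions the command-line front end
# (inst/cli/bioschemarkup.R) calls; they are equally usable from R.

#' Convert a JATS record (plus optional annotations) to JSON-LD markup
#'
#' Runs the full pipeline: parse the JATS article, optionally parse a
#' PubAnnotation document and aggregate its denotations into per-term
#' occurrence counts (dropping terms below `min_occurrences`), build the
#' entity graph, validate it against the profile registry (summary on
#' standard error), and write or return the serialized JSON-LD.
#'
#' @param jats_path Path to the JATS XML file (bare article or OAI-PMH
#'   envelope).
#' @param annotations_path Optional path to a PubAnnotation JSON file.
#' @param labels_path Optional path to a two-column TSV term-label map.
#' @param base_iri Base IRI for minted node identifiers.
#' @param min_occurrences Drop terms annotated fewer than this many times
#'   (1 keeps every term; 2 keeps terms with more than one occurrence).
#' @param out_path Output file for the JSON-LD; `NULL` returns the text.
#' @param prefix_map CURIE prefix map for term expansion.
#' @return Invisibly, a list with `markup` (the [markup_document]),
#'   `report` (the [validate_document()] result) and `jsonld` (the text).
#' @export
run_convert <- function(jats_path, annotations_path = NULL,
                        labels_path = NULL,
                        base_iri = "https://biotea.github.io/bioschemas",
                        min_occurrences = 1, out_path = NULL,
                        prefix_map = default_prefix_map()) {
  art <- parse_jats(jats_path)
  aggregates <- NULL
  if (!is.null(annotations_path)) {
    labels <- if (!is.null(labels_path)) read_label_map(labels_path)
    set <- parse_pubannotation(annotations_path)
    aggregates <- aggregate_terms(set, labels = labels,
                                  prefix_map = prefix_map) |>
      filter_by_occurrence(min_occurrences)
  }
  doc <- build_markup(art$metadata, art$periodical, aggregates,
                      policy = iri_policy(base_iri))
  report <- validate_document(doc)
  message("conformance: ",
          if (report$conformant) "OK" else "FAILED",
          " (", report$checked_nodes, " nodes, ",
          sum(report$issues$severity == "error"), " errors, ",
          sum(report$issues$severity == "warning"), " warnings)")
  jsonld <- serialize_jsonld(doc)
  if (!is.null(out_path)) {
    writeLines(jsonld, out_path, useBytes = TRUE)
  }
  invisible(list(markup = doc, report = report, jsonld = jsonld))
}

#' Validate an emitted JSON-LD file against the profile registry
#'
#' @param jsonld_path Path to a JSON-LD file in the shape written by
#'   [serialize_jsonld()].
#' @param strict Treat warnings as failures too.
#' @return Invisibly, a list with `report` and `status`: 0 when conformant
#'   (and, under `strict`, warning-free), 1 otherwise. Unparseable input is
#'   an error.
#' @export
run_validate <- function(jsonld_path, strict = FALSE) {
  doc <- parse_jsonld(jsonld_path)
  report <- validate_document(doc)
  print(report)
  ok <- report$conformant &&
    (!strict || !any(report$issues$severity == "warning"))
  invisible(list(report = report, status = if (ok) 0L else 1L))
}
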