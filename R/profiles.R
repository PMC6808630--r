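# Profile registry: the five draft Bioschemas literature profiles and
# conformance checking of markup documents against their property tiers.

the <- new.env(parent = emptyenv())

#' The bundled profile tier table
#'
#' The five draft literature profiles (Journal, Volume, Issue,
#' ScholarlyArticle, SemanticAnnotation) are shipped as a plain TSV so the
#' tier membership can be edited as the community drafts evolve, without
#' touching code. Each row assigns one property of one profile to one tier.
#'
#' @return A tibble with columns `profile`, `entity_type`, `tier`
#'   (`minimum`/`recommended`/`optional`) and `property`, in file order.
#' @examples
#' bioschemas_profiles()
#' @export
bioschemas_profiles <- function() {
  if (is.null(the$profiles)) {
    path <- system.file("extdata", "profiles.tsv", package = "bioschemarkup",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character")
    the$profiles <- tibble::as_tibble(tab)
  }
  the$profiles
}

profile_names <- function() unique(bioschemas_profiles()$profile)

#' Look up one profile specification
#'
#' @param profile_name One of `"Journal"`, `"Volume"`, `"Issue"`,
#'   `"ScholarlyArticle"`, `"SemanticAnnotation"`.
#' @return A `profile_spec` object: a list with `profile_name`,
#'   `entity_type` (the schema.org type the profile constrains), and the
#'   three pairwise-disjoint character vectors `minimum`, `recommended`,
#'   `optional`.
#' @examples
#' get_profile("ScholarlyArticle")$entity_type
#' get_profile("Journal")$minimum
#' @export
get_profile <- function(profile_name) {
  tab <- bioschemas_profiles()
  if (!is.character(profile_name) || length(profile_name) != 1 ||
      !profile_name %in% tab$profile) {
    stop("unknown profile '", paste(profile_name, collapse = ","),
         "'; valid profiles: ", paste(profile_names(), collapse = ", "),
         call. = FALSE)
  }
  rows <- tab[tab$profile == profile_name, ]
  structure(
    list(
      profile_name = profile_name,
      entity_type = rows$entity_type[[1]],
      minimum = rows$property[rows$tier == "minimum"],
      recommended = rows$property[rows$tier == "recommended"],
      optional = rows$property[rows$tier == "optional"]
    ),
    class = "profile_spec"
  )
}

#' @export
print.profile_spec <- function(x, ...) {
  cat("<profile_spec> ", x$profile_name, " (schema:", x$entity_type, ")\n",
      sep = "")
  cat("  minimum:     ", paste(x$minimum, collapse = ", "), "\n", sep = "")
  cat("  recommended: ", paste(x$recommended, collapse = ", "), "\n", sep = "")
  cat("  optional:    ", paste(x$optional, collapse = ", "), "\n", sep = "")
  invisible(x)
}

profile_for_type <- function(entity_type) {
  tab <- bioschemas_profiles()
  hit <- unique(tab$profile[tab$entity_type == entity_type])
  if (length(hit) == 0) return(NULL)
  get_profile(hit[[1]])
}

severity_levels <- c("error", "warning", "info")

conformance_issue <- function(severity, node_id, property, message) {
  tibble::tibble(severity = severity, node_id = node_id,
                 property = property, message = message)
}

empty_issues <- function() {
  tibble::tibble(severity = character(), node_id = character(),
                 property = character(), message = character())
}

#' Check one entity node against a profile's property tiers
#'
#' Emits one issue per tiered property that is missing or empty on the node:
#' a missing minimum-tier property is an `error`, a missing recommended-tier
#' property a `warning`. Empty strings and empty lists count as missing.
#' Optional-tier omissions are reported (as `info`) only when
#' `include_optional = TRUE`; a node carrying every minimum and recommended
#' property yields zero issues by default.
#'
#' @param node An `entity_node` (as found in a [markup_document]).
#' @param spec A `profile_spec` from [get_profile()]; its `entity_type` must
#'   match the node's declared type (a mismatch is a usage error, not an
#'   issue).
#' @param include_optional Report missing optional-tier properties as `info`.
#' @return A tibble of issues with columns `severity`, `node_id`,
#'   `property`, `message`, ordered by (severity, property name); zero rows
#'   when the node satisfies the checked tiers.
#' @export
validate_node <- function(node, spec, include_optional = FALSE) {
  stopifnot(inherits(spec, "profile_spec"))
  if (!inherits(node, "entity_node")) {
    stop("`node` must be an entity_node", call. = FALSE)
  }
  if (!identical(node$type, spec$entity_type)) {
    stop("node type '", node$type, "' does not match profile entity type '",
         spec$entity_type, "'", call. = FALSE)
  }
  tiers <- list(error = spec$minimum, warning = spec$recommended)
  if (isTRUE(include_optional)) tiers$info <- spec$optional
  issues <- empty_issues()
  for (sev in names(tiers)) {
    for (prop in sort_c(tiers[[sev]])) {
      if (is_empty_value(node$properties[[prop]])) {
        tier <- c(error = "minimum", warning = "recommended",
                  info = "optional")[[sev]]
        issues <- dplyr::bind_rows(issues, conformance_issue(
          sev, node$id, prop,
          sprintf("%s-tier property '%s' is missing or empty on %s node <%s>",
                  tier, prop, node$type, node$id)
        ))
      }
    }
  }
  issues[order(match(issues$severity, severity_levels)), , drop = FALSE]
}

#' Validate a whole markup document against the profile registry
#'
#' Every node whose schema.org type matches a registered profile is checked
#' with [validate_node()]; nodes of unregistered types are skipped and
#' counted separately. The top-level CreativeWork record node is
#' structured-data plumbing (it only points at the publication via
#' `mainEntity`) and is never validated against a profile.
#'
#' @param doc A [markup_document].
#' @inheritParams validate_node
#' @return A `conformance_report`: list with `issues` (tibble as in
#'   [validate_node()]), `checked_nodes`, `skipped_nodes`, and `conformant`
#'   (`TRUE` iff no error-severity issue).
#' @seealso [tidy.conformance_report()], [glance.conformance_report()]
#' @export
validate_document <- function(doc, include_optional = FALSE) {
  stopifnot(inherits(doc, "markup_document"))
  nodes <- c(list(doc$article), doc$periodical_chain, doc$annotations)
  issues <- empty_issues()
  checked <- 0L
  skipped <- 1L  # the record node, exempt by design
  for (node in nodes) {
    spec <- profile_for_type(node$type)
    if (is.null(spec)) {
      skipped <- skipped + 1L
      next
    }
    checked <- checked + 1L
    issues <- dplyr::bind_rows(issues,
                               validate_node(node, spec, include_optional))
  }
  structure(
    list(
      issues = issues,
      checked_nodes = checked,
      skipped_nodes = skipped,
      conformant = !any(issues$severity == "error")
    ),
    class = "conformance_report"
  )
}

#' @export
print.conformance_report <- function(x, ...) {
  n_err <- sum(x$issues$severity == "error")
  n_warn <- sum(x$issues$severity == "warning")
  cat("<conformance_report> ",
      if (x$conformant) "conformant" else "NOT conformant",
      ": ", x$checked_nodes, " node(s) checked, ",
      n_err, " error(s), ", n_warn, " warning(s)\n", sep = "")
  if (nrow(x$issues) > 0) print(x$issues, ...)
  invisible(x)
}
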