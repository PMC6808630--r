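# Tidier and plotting surface for report and document objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conformance report into its issue table
#'
#' @param x A `conformance_report` from [validate_document()].
#' @param ... Unused.
#' @return The issues tibble (`severity`, `node_id`, `property`,
#'   `message`), zero rows for a clean document.
#' @exportS3Method generics::tidy
tidy.conformance_report <- function(x, ...) x$issues

#' One-row summary of a conformance report
#'
#' @inheritParams tidy.conformance_report
#' @return A one-row tibble: `checked_nodes`, `skipped_nodes`, `n_errors`,
#'   `n_warnings`, `conformant`.
#' @exportS3Method generics::glance
glance.conformance_report <- function(x, ...) {
  tibble::tibble(
    checked_nodes = x$checked_nodes,
    skipped_nodes = x$skipped_nodes,
    n_errors = sum(x$issues$severity == "error"),
    n_warnings = sum(x$issues$severity == "warning"),
    conformant = x$conformant
  )
}

#' Tidy a markup document into a node table
#'
#' @param x A [markup_document].
#' @param ... Unused.
#' @return A tibble with one row per entity node: `node_id`, `node_type`,
#'   `n_properties`.
#' @exportS3Method generics::tidy
tidy.markup_document <- function(x, ...) {
  nodes <- all_nodes(x)
  tibble::tibble(
    node_id = vapply(nodes, function(n) n$id, character(1)),
    node_type = vapply(nodes, function(n) n$type, character(1)),
    n_properties = vapply(nodes, function(n) length(n$properties),
                          integer(1))
  )
}

#' One-row summary of a markup document
#'
#' @inheritParams tidy.markup_document
#' @return A one-row tibble: `article_id`, `n_nodes`, `chain_length`,
#'   `n_annotations`.
#' @exportS3Method generics::glance
glance.markup_document <- function(x, ...) {
  tibble::tibble(
    article_id = x$article$id,
    n_nodes = length(all_nodes(x)),
    chain_length = length(x$periodical_chain),
    n_annotations = length(x$annotations)
  )
}

#' Plot conformance issues by severity and node
#'
#' @param object A `conformance_report`.
#' @param ... Unused.
#' @return A ggplot: issue counts per node, filled by severity; an
#'   annotated empty plot for a clean report.
#' @exportS3Method ggplot2::autoplot
autoplot.conformance_report <- function(object, ...) {
  issues <- object$issues
  if (nrow(issues) == 0) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "No issues") +
        ggplot2::theme_void()
    )
  }
  issues$severity <- factor(issues$severity, levels = severity_levels)
  ggplot2::ggplot(issues,
                  ggplot2::aes(y = .data$node_id, fill = .data$severity)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "issues", y = NULL, fill = "severity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot term occurrence counts
#'
#' A bar-per-term view of an aggregate table -- the quantitative
#' counterpart of rendering frequently annotated terms as a word cloud.
#'
#' @param aggregates Tibble from [aggregate_terms()].
#' @param min_occurrences Optional threshold applied via
#'   [filter_by_occurrence()] before plotting.
#' @return A ggplot.
#' @export
plot_term_occurrences <- function(aggregates, min_occurrences = 1) {
  shown <- filter_by_occurrence(aggregates, min_occurrences)
  shown$label <- factor(shown$label,
                        levels = rev(unique(shown$label)))
  ggplot2::ggplot(shown,
                  ggplot2::aes(x = .data$occurrences, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "occurrences", y = NULL) +
    ggplot2::theme_minimal()
}
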