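# Build a complete markup document (all mapped fields populated, with
# annotations) from the synthetic generators.
complete_markup <- function(seed = 1,
                            mult = c("GO:0008150" = 3, "CHEBI:15377" = 1),
                            has_volume = TRUE, has_issue = TRUE,
                            base_iri = "https://example.org/bioschemas") {
  art <- parse_jats(make_jats_fixture(seed = seed, has_volume = has_volume,
                                      has_issue = has_issue))
  agg <- aggregate_terms(parse_pubannotation(
    make_pubannotation_fixture(seed = seed, term_multiplicities = mult)))
  build_markup(art$metadata, art$periodical, agg,
               policy = iri_policy(base_iri))
}

node_by_id <- function(doc, id) {
  for (n in c(list(doc$record, doc$article), doc$periodical_chain,
              doc$annotations)) {
    if (identical(n$id, id)) return(n)
  }
  NULL
}
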