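test_that("PubAnnotation documents load with spans validated", {
  empty <- parse_pubannotation('{"text": "abc", "denotations": []}')
  expect_identical(nrow(empty$denotations), 0L)

  fx <- make_pubannotation_fixture(
    seed = 2, term_multiplicities = c("GO:0008150" = 3, "CHEBI:15377" = 1))
  set <- parse_pubannotation(fx)
  expect_identical(set$source_db, "PMC")
  expect_identical(set$source_id, "2628047")
  expect_identical(nrow(set$denotations), 4L)
  expect_false(anyDuplicated(set$denotations$id) > 0)

  # spans 0-based end-exclusive, in bounds, document order preserved
  expect_true(all(set$denotations$begin >= 0))
  expect_true(all(set$denotations$end <= nchar(set$text)))
  expect_true(all(set$denotations$begin < set$denotations$end))
})

test_that("degenerate and out-of-bounds spans are rejected by id", {
  expect_error(parse_pubannotation(
    '{"text":"abcdef","denotations":[{"id":"T1","span":{"begin":5,"end":5},"obj":"X:1"}]}'),
    "T1")
  expect_error(parse_pubannotation(
    '{"text":"abc","denotations":[{"id":"T9","span":{"begin":1,"end":9},"obj":"X:1"}]}'),
    "T9.*beyond")
  expect_error(parse_pubannotation("{nope"), "malformed")
  expect_error(parse_pubannotation(
    '{"denotations":[{"id":"T1","span":{"begin":0,"end":1},"obj":""}]}'),
    "empty term")
  expect_error(parse_pubannotation(
    '{"denotations":[{"id":"T1","span":{"begin":0,"end":1},"obj":"A"},{"id":"T1","span":{"begin":2,"end":3},"obj":"B"}]}'),
    "duplicate")
})

test_that("expand_term handles CURIEs, absolute IRIs and unknown prefixes", {
  expect_identical(
    expand_term("GO:0008150", c(GO = "http://purl.obolibrary.org/obo/GO_")),
    "http://purl.obolibrary.org/obo/GO_0008150")
  expect_identical(expand_term("http://example.org/T1", character(0)),
                   "http://example.org/T1")
  expect_warning(out <- expand_term("XX:1", character(0)), "XX")
  expect_identical(out, "XX:1")
  expect_error(expand_term(""), "empty term")
  # idempotent once expanded
  iri <- expand_term("GO:0008150")
  expect_identical(expand_term(iri), iri)
})

test_that("aggregation counts occurrences per expanded term", {
  json <- '{"text":"aaaa bbbb cccc dddd eeee ffff gggg hhhh",
            "denotations":[
              {"id":"T1","span":{"begin":0,"end":4},"obj":"X:A"},
              {"id":"T2","span":{"begin":5,"end":9},"obj":"X:B"},
              {"id":"T3","span":{"begin":20,"end":24},"obj":"X:A"},
              {"id":"T4","span":{"begin":30,"end":34},"obj":"X:A"}]}'
  set <- parse_pubannotation(json)
  agg <- aggregate_terms(set, prefix_map = c(X = "http://x.org/term/"))
  # oracle: brute-force count over the denotation list
  expect_identical(agg$term_iri,
                   c("http://x.org/term/A", "http://x.org/term/B"))
  expect_identical(agg$occurrences, c(3L, 1L))
  expect_identical(agg$first_offset, c(0L, 5L))
  expect_identical(sum(agg$occurrences), nrow(set$denotations))
  expect_identical(agg$label, c("A", "B"))
  expect_identical(agg$ontology_hint,
                   rep("http://x.org/term/", 2))
})

test_that("labels come from the map with local-name fallback", {
  json <- '{"denotations":[
    {"id":"T1","span":{"begin":0,"end":4},"obj":"GO:0008150"},
    {"id":"T2","span":{"begin":5,"end":9},"obj":"X:9"}]}'
  set <- parse_pubannotation(json)
  agg <- suppressWarnings(aggregate_terms(
    set,
    labels = c("http://purl.obolibrary.org/obo/GO_0008150" =
                 "biological process")))
  # the passed-through CURIE has no /, # or _ separator: it is its own label
  expect_setequal(agg$label, c("biological process", "X:9"))
})

test_that("aggregate order is (occurrences desc, term_iri asc) and ties break bytewise", {
  json <- '{"denotations":[
    {"id":"T1","span":{"begin":0,"end":1},"obj":"http://x.org/b"},
    {"id":"T2","span":{"begin":2,"end":3},"obj":"http://x.org/a"},
    {"id":"T3","span":{"begin":4,"end":5},"obj":"http://x.org/c"},
    {"id":"T4","span":{"begin":6,"end":7},"obj":"http://x.org/c"}]}'
  agg <- aggregate_terms(parse_pubannotation(json))
  expect_identical(agg$term_iri,
                   c("http://x.org/c", "http://x.org/a", "http://x.org/b"))
})

test_that("aggregation of empty sets yields an empty typed tibble", {
  agg <- aggregate_terms(parse_pubannotation('{"denotations":[]}'))
  expect_identical(nrow(agg), 0L)
  expect_named(agg, c("term_iri", "label", "occurrences", "first_offset",
                      "ontology_hint"))
})

test_that("occurrence filtering keeps order and counts, rejects bad thresholds", {
  fx <- make_pubannotation_fixture(
    seed = 4, term_multiplicities = c("X:A" = 3, "X:B" = 1))
  agg <- suppressWarnings(aggregate_terms(parse_pubannotation(fx)))
  expect_identical(nrow(filter_by_occurrence(agg, 2)), 1L)
  expect_identical(filter_by_occurrence(agg, 2)$occurrences, 3L)
  expect_identical(filter_by_occurrence(agg, 1), agg)
  expect_identical(nrow(filter_by_occurrence(agg, 4)), 0L)
  expect_error(filter_by_occurrence(agg, 0), "positive")
})

test_that("re-aggregating reconstructed denotations is idempotent", {
  for (seed in 1:10) {
    mult <- c("GO:0008150" = (seed %% 4) + 1, "CHEBI:15377" = (seed %% 3) + 1,
              "http://x.org/t" = 1)
    set <- parse_pubannotation(make_pubannotation_fixture(
      seed = seed, term_multiplicities = mult))
    agg <- aggregate_terms(set)
    # rebuild a denotation list from the aggregates and re-aggregate
    rebuilt <- set
    rebuilt$denotations <- tibble::tibble(
      id = paste0("R", seq_len(sum(agg$occurrences))),
      begin = seq_len(sum(agg$occurrences)) * 10L,
      end = seq_len(sum(agg$occurrences)) * 10L + 2L,
      term = rep(agg$term_iri, agg$occurrences)
    )
    rebuilt$text <- NULL
    agg2 <- aggregate_terms(rebuilt)
    expect_identical(agg2$term_iri, agg$term_iri)
    expect_identical(agg2$occurrences, agg$occurrences)
  }
})
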