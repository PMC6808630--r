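test_that("registry holds exactly the five literature profiles with sound tiers", {
  tab <- bioschemas_profiles()
  profiles <- unique(tab$profile)
  expect_length(profiles, 5)
  expect_setequal(profiles, c("Journal", "Volume", "Issue",
                              "ScholarlyArticle", "SemanticAnnotation"))
  for (p in profiles) {
    spec <- get_profile(p)
    expect_s3_class(spec, "profile_spec")
    # minimum tier non-empty, tiers pairwise disjoint
    expect_gt(length(spec$minimum), 0)
    expect_length(intersect(spec$minimum, spec$recommended), 0)
    expect_length(intersect(spec$minimum, spec$optional), 0)
    expect_length(intersect(spec$recommended, spec$optional), 0)
  }
  expect_identical(get_profile("ScholarlyArticle")$entity_type,
                   "ScholarlyArticle")
  expect_true("name" %in% get_profile("Journal")$minimum)
})

test_that("unknown profile names fail with the valid options listed", {
  expect_error(get_profile("Book"), "Journal.*SemanticAnnotation")
  expect_error(get_profile(1))
})

test_that("validate_node flags missing tiered properties at the right severity", {
  doc <- complete_markup(seed = 11)
  spec <- get_profile("ScholarlyArticle")
  node <- doc$article

  expect_identical(nrow(validate_node(node, spec)), 0L)

  # oracle: tier-wise set difference between property keys and the tier list
  missing_min <- setdiff(spec$minimum, names(node$properties))
  expect_length(missing_min, 0)

  broken <- node
  broken$properties$name <- NULL
  issues <- validate_node(broken, spec)
  expect_identical(nrow(issues), 1L)
  expect_identical(issues$severity, "error")
  expect_identical(issues$property, "name")
  expect_match(issues$message, "name")

  no_license <- node
  no_license$properties$license <- NULL
  issues <- validate_node(no_license, spec)
  expect_identical(nrow(issues), 1L)
  expect_identical(issues$severity, "warning")
  expect_identical(issues$property, "license")
})

test_that("empty-valued properties count as missing", {
  doc <- complete_markup(seed = 12)
  spec <- get_profile("ScholarlyArticle")
  for (empty in list("", list(), NULL)) {
    node <- doc$article
    node$properties$name <- empty
    issues <- validate_node(node, spec)
    expect_identical(issues$property, "name")
    expect_identical(issues$severity, "error")
  }
})

test_that("issues are ordered by severity then property name", {
  doc <- complete_markup(seed = 13)
  node <- doc$article
  node$properties[c("name", "author", "license", "about")] <- NULL
  issues <- validate_node(node, get_profile("ScholarlyArticle"))
  expect_identical(issues$severity, c("error", "error", "warning", "warning"))
  expect_identical(issues$property, c("author", "name", "about", "license"))
})

test_that("node/profile type mismatch is a usage error, not an issue", {
  doc <- complete_markup(seed = 14)
  expect_error(validate_node(doc$article, get_profile("Journal")),
               "does not match")
})

test_that("removing properties never decreases the issue count", {
  doc <- complete_markup(seed = 15)
  spec <- get_profile("ScholarlyArticle")
  base_n <- nrow(validate_node(doc$article, spec))
  for (prop in names(doc$article$properties)) {
    node <- doc$article
    node$properties[[prop]] <- NULL
    expect_gte(nrow(validate_node(node, spec)), base_n)
  }
})

test_that("validate_document checks typed nodes, skips the record node", {
  doc <- complete_markup(seed = 16)
  rep <- validate_document(doc)
  expect_true(rep$conformant)
  expect_identical(nrow(rep$issues), 0L)
  # article + issue + volume + periodical + 2 annotations
  expect_identical(rep$checked_nodes, 6L)
  expect_identical(rep$skipped_nodes, 1L)

  # two annotation nodes each stripped of "name" -> exactly 2 errors
  broken <- doc
  broken$annotations <- lapply(broken$annotations, function(a) {
    a$properties$name <- NULL
    a
  })
  rep2 <- validate_document(broken)
  expect_false(rep2$conformant)
  expect_identical(sum(rep2$issues$severity == "error"), 2L)
  expect_true(all(rep2$issues$property[rep2$issues$severity == "error"] ==
                    "name"))
})

test_that("validation is pure: the serialized document is unchanged", {
  doc <- complete_markup(seed = 17)
  before <- serialize_jsonld(doc)
  invisible(validate_document(doc))
  expect_identical(serialize_jsonld(doc), before)
})

test_that("tidy/glance/autoplot expose the report tidily", {
  rep <- validate_document(complete_markup(seed = 18))
  expect_identical(tidy(rep), rep$issues)
  g <- glance(rep)
  expect_identical(g$n_errors, 0L)
  expect_true(g$conformant)
  expect_s3_class(autoplot(rep), "ggplot")
})
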