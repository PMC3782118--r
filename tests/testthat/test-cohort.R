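test_that("keyword screening is case-insensitive substring over name, indication and descriptions", {
  ds <- tiny_dataset()
  expect_equal(keyword_screen(ds, "schizophrenia"), "SYN00001")
  expect_equal(keyword_screen(ds, "SCHIZOPHRENIA"), "SYN00001")
  # inflection via substring: "schizophrenic" hits "schizophrenics"
  ds2 <- ddi_dataset(
    data.frame(drug_id = c("A1", "B1"), name = c("a", "b"),
               indication = c("Used in schizophrenics.", "For gout.")),
    interactions = data.frame(drug_id = "B1", partner_id = "A1",
                              description = "Sedation in schizophrenic patients."))
  hits <- keyword_screen(ds2, "schizophrenic")
  # brute-force scan of every text field
  brute <- c(
    ds2$drugs$drug_id[grepl("schizophrenic", tolower(paste(
      ds2$drugs$name, ds2$drugs$indication)), fixed = TRUE)],
    ds2$interactions$drug_id[grepl("schizophrenic",
                                   tolower(ds2$interactions$description),
                                   fixed = TRUE)])
  expect_setequal(hits, unique(brute))
  expect_error(keyword_screen(ds, character()), "non-empty")
})

test_that("keyword screening is monotone in the keyword list", {
  ds <- small_dataset(3)$dataset
  kws <- c("schizophrenia", "schizophrenic", "depressive", "diabetes")
  prev <- character()
  for (k in seq_along(kws)) {
    cur <- keyword_screen(ds, kws[seq_len(k)])
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("indication filtering keeps only indication-field hits", {
  ds <- ddi_dataset(
    data.frame(drug_id = c("A1", "B1"), name = c("a", "b"),
               indication = c("For schizophrenia.", "For gout.")),
    interactions = data.frame(drug_id = "B1", partner_id = "A1",
                              description = "Risk in schizophrenia patients."))
  screened <- keyword_screen(ds, "schizophrenia")
  expect_setequal(screened, c("A1", "B1"))   # B1 hit only via description
  expect_equal(indication_filter(ds, screened, "schizophrenia"), "A1")
  expect_error(indication_filter(ds, "Z9", "schizophrenia"), "outside")
})

test_that("cohort resolution applies include then exclude with a full audit", {
  indicated <- sprintf("D%02d", 1:38)
  def <- cohort_definition(exclude = indicated[1:5])
  res <- resolve_cohort(indicated, indicated, def)
  expect_equal(length(res$final), 33L)

  def2 <- cohort_definition(include = c("X1", "X2"), exclude = indicated[1:5])
  res2 <- resolve_cohort(indicated, indicated, def2)
  expect_equal(length(res2$final), 35L)
  expect_setequal(res2$audit$drug_id[res2$audit$tag == "manual-include"],
                  c("X1", "X2"))
  # audit tags partition the final set (plus the exclusions)
  final_tags <- res2$audit[res2$audit$tag != "manual-exclude", ]
  expect_setequal(final_tags$drug_id, res2$final)
  expect_false(anyDuplicated(final_tags$drug_id) > 0)

  expect_warning(resolve_cohort(indicated, indicated,
                                cohort_definition(exclude = "NOPE")),
                 "no effect")
  expect_error(cohort_definition(include = "A", exclude = "A"), "overlap")
})

test_that("typology labeling restricts to the cohort and flags gaps", {
  fx <- reference_tables()
  labels <- stats::setNames(fx$table1$typology, fx$table1$drug_id)
  ty <- label_typology(fx$table1$drug_id, labels)
  expect_equal(sum(ty == "typical"), 18L)
  expect_equal(sum(ty == "atypical"), 10L)
  expect_length(attr(ty, "unlabeled"), 0L)

  expect_equal(length(suppressWarnings(label_typology(character(), labels))),
               0L)
  expect_warning(label_typology(fx$table1$drug_id[1:2], labels), "ignored")
  expect_error(suppressWarnings(label_typology(c(fx$table1$drug_id[1], "ZZ"),
                                               labels,
                                               require_complete = TRUE)),
               "ZZ")
  expect_error(label_typology("A", c(A = "weird")), "typical")
})
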