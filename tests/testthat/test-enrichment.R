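# hand-built subnetwork: cohort T1 (typical), A1 (atypical); partners with
# known annotations
enrichment_fixture <- function() {
  ds <- ddi_dataset(
    data.frame(drug_id = c("T1", "A1", "P1", "P2", "P3"),
               name = letters[1:5], indication = ""),
    interactions = data.frame(
      drug_id = c("T1", "T1", "T1", "A1", "T1"),
      partner_id = c("P1", "P2", "P3", "P1", "A1"),
      description = ""),
    atc_codes = list(T1 = "N05AA01", A1 = "N05AH02",
                     P1 = "J01MA02",
                     P2 = c("A02BC01", "N05AH02")))  # P3 unannotated
  net <- build_ddi_network(ds)
  list(ds = ds, sub = extract_scz_subnetwork(net, c("T1", "A1")))
}

test_that("interaction categorization counts one link per distinct partner class", {
  fx <- enrichment_fixture()
  ct <- categorize_interactions(fx$sub, "T1", fx$ds$atc_codes, level = 1,
                                name = "typical")
  # P1 -> J; P2 -> A and N (multi-code partner counts twice); P3 unclassified
  expect_equal(ct$counts, c(A = 1L, J = 1L, N = 1L))
  expect_equal(ct$classified_total, 3L)
  expect_equal(ct$unclassified, 1L)

  # intra-cohort edge T1-A1 excluded by default, included on request
  ct2 <- categorize_interactions(fx$sub, "T1", fx$ds$atc_codes, level = 1,
                                 include_intra = TRUE, name = "typical")
  expect_equal(ct2$counts[["N"]], 2L)
  expect_equal(ct2$classified_total, 4L)

  ct3 <- categorize_interactions(fx$sub, "T1", fx$ds$atc_codes, level = 3,
                                 name = "typical")
  expect_equal(ct3$counts, c(A02B = 1L, J01M = 1L, N05A = 1L))

  expect_error(categorize_interactions(fx$sub, character(), fx$ds$atc_codes),
               "non-empty")
  expect_error(categorize_interactions(fx$sub, "P1", fx$ds$atc_codes),
               "outside the cohort")
})

test_that("subgroup comparison emits the union of categories with consistent directions", {
  fx <- enrichment_fixture()
  ca <- categorize_interactions(fx$sub, "T1", fx$ds$atc_codes, 1,
                                name = "typical")
  cb <- categorize_interactions(fx$sub, "A1", fx$ds$atc_codes, 1,
                                name = "atypical")
  enr <- compare_subgroups(ca, cb)
  expect_setequal(enr$category, c("A", "J", "N"))   # union; J present in both
  expect_equal(enr$r[enr$category == "A"], 0L)      # absent -> zero count
  expect_equal(enr$p_adjusted, pmin(1, enr$p_raw * nrow(enr)))
  for (i in seq_len(nrow(enr))) {
    expected <- if (enr$n[i] / enr$N[i] > enr$r[i] / enr$R[i]) "typical-enriched"
    else if (enr$r[i] / enr$R[i] > enr$n[i] / enr$N[i]) "atypical-enriched"
    else "none"
    expect_equal(enr$direction[i], expected)
  }

  ca3 <- categorize_interactions(fx$sub, "T1", fx$ds$atc_codes, 3,
                                 name = "typical")
  expect_error(compare_subgroups(ca3, cb), "different ATC levels")
})

test_that("reported percentages use two decimals, rounding half up", {
  expect_equal(round_half_up(74 / 638 * 100), 11.60)
  expect_equal(round_half_up(5 / 258 * 100), 1.94)
  expect_equal(round_half_up(119 / 258 * 100), 46.12)
  expect_equal(round_half_up(0.005, 2), 0.01)  # exact half rounds up
})

test_that("category overlap partitions observed categories by presence", {
  mk <- function(counts, name) structure(
    list(level = 3L, name = name, counts = counts,
         classified_total = sum(counts), unclassified = 0L),
    class = "interaction_categories")
  a <- mk(c(X01A = 3L), "typical")
  b <- mk(c(X01A = 1L, Y02B = 2L), "atypical")
  ov <- category_overlap(a, b)
  expect_equal(ov, list(common = "X01A", specific_a = character(),
                        specific_b = "Y02B"))

  dj <- category_overlap(mk(c(X01A = 1L), "t"), mk(c(Y02B = 1L), "a"))
  expect_length(dj$common, 0L)

  # planted 39 common / 18 specific-typical / 5 specific-atypical structure
  common <- sprintf("C%02dA", 1:39)
  spec_t <- sprintf("T%02dA", 1:18)
  spec_a <- sprintf("A%02dA", 1:5)
  a2 <- mk(stats::setNames(rep(1L, 57), c(common, spec_t)), "typical")
  b2 <- mk(stats::setNames(rep(1L, 44), c(common, spec_a)), "atypical")
  ov2 <- category_overlap(a2, b2)
  expect_length(ov2$common, 39L)
  expect_length(ov2$specific_a, 18L)
  expect_length(ov2$specific_b, 5L)
  # disjoint cover of the union
  expect_setequal(c(ov2$common, ov2$specific_a, ov2$specific_b),
                  union(c(common, spec_t), c(common, spec_a)))
})
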