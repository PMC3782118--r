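test_that("generation is deterministic under seed and varies across seeds", {
  a <- generate_dataset(synthetic_config(seed = 404))
  b <- generate_dataset(synthetic_config(seed = 404))
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth$cohort, b$truth$cohort)
  c <- generate_dataset(synthetic_config(seed = 405))
  expect_false(identical(a$dataset$interactions, c$dataset$interactions))

  # byte-identical on disk
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_ddi_dataset(a$dataset, fa, "tsv")
  write_ddi_dataset(b$dataset, fb, "tsv")
  expect_identical(readLines(fa), readLines(fb))
})

test_that("generated datasets have no dangling partners and no self-loops", {
  for (seed in 1:100) {
    g <- small_dataset(seed)
    rep <- validate_ddi_dataset(g$dataset)
    expect_equal(rep$n_dangling_partners, 0L)
    expect_equal(rep$n_self_loops_removed, 0L)
  }
})

test_that("default config plants the 46/38 screening funnel", {
  g <- generate_dataset(synthetic_config(seed = 17))
  screened <- keyword_screen(g$dataset)
  indicated <- indication_filter(g$dataset, screened)
  expect_length(screened, 46L)
  expect_length(indicated, 38L)
  res <- resolve_cohort(screened, indicated,
                        cohort_definition(exclude = g$truth$decoy_ids))
  expect_length(res$final, 33L)
  # the analysis cohort: final members that take part in interactions
  net <- build_ddi_network(g$dataset)
  expect_length(intersect(res$final, igraph::V(net$graph)$name), 28L)
  # cohort drugs carry the disease keyword in their indication
  ind <- g$dataset$drugs$indication[
    g$dataset$drugs$drug_id %in% g$truth$cohort$drug_id]
  expect_true(all(grepl("schizo", ind)))
})

test_that("realized cohort mean degree tracks the configured expectation", {
  means <- vapply(1:40, function(seed) {
    g <- generate_dataset(synthetic_config(seed = seed))
    net <- build_ddi_network(g$dataset)
    partition_mean_degree(extract_scz_subnetwork(net, g$truth$cohort$drug_id))
  }, numeric(1))
  expect_lt(abs(mean(means) - 36.93) / 36.93, 0.10)
})

test_that("partner categories follow the configured weights without planted effects", {
  cfg <- synthetic_config(seed = 2024, multi_code_prob = 0,
                          partner_unannotated_prob = 0)
  g <- generate_dataset(cfg)
  net <- build_ddi_network(g$dataset)
  sub <- extract_scz_subnetwork(net, g$truth$cohort$drug_id)
  ct <- categorize_interactions(sub, g$truth$cohort$drug_id,
                                g$dataset$atc_codes, level = 1,
                                name = "all")
  obs <- stats::setNames(rep(0L, 14), names(cfg$atc_level1_weights))
  obs[names(ct$counts)] <- ct$counts
  gof <- stats::chisq.test(obs, p = cfg$atc_level1_weights)
  expect_gt(gof$p.value, 1e-3)
})

test_that("planted effects tilt only the typical subgroup's selection odds", {
  cfg <- synthetic_config(seed = 5, planted_effects = c(A = 6))
  g <- generate_dataset(cfg)
  pt <- g$truth$category_probs$typical
  pa <- g$truth$category_probs$atypical
  expect_gt(pt[["A"]] / pa[["A"]], 4)  # odds multiplier raises A for typical
  expect_equal(sum(pt), 1, tolerance = 1e-12)
  expect_equal(sum(pa), 1, tolerance = 1e-12)
  expect_equal(pa[["A"]] / (1 - cfg$partner_unannotated_prob),
               cfg$atc_level1_weights[["A"]], tolerance = 1e-12)
})

test_that("infeasible configs are rejected", {
  expect_error(synthetic_config(n_cohort = 50, n_drugs = 40), "n_cohort")
  expect_error(synthetic_config(typical_fraction = 1.2), "probabilities")
  expect_error(synthetic_config(planted_effects = c(Z = 2)), "planted_effects")
  expect_error(synthetic_config(atc_level1_weights = c(A = 1)), "14")
  expect_error(synthetic_config(degree_model = list(family = "weibull")),
               "family")
})
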