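test_that("pair formation ignores direction and drops self-loops", {
  # reciprocal declarations collapse to one edge
  ds <- tiny_dataset()
  net <- build_ddi_network(ds)
  expect_equal(nrow(net$edges), 1L)

  # a one-sided declaration still forms the pair
  ds1 <- ddi_dataset(
    data.frame(drug_id = c("A1", "B1"), name = c("a", "b"),
               indication = c("", "")),
    interactions = data.frame(drug_id = "A1", partner_id = "B1",
                              description = "one-sided"))
  expect_equal(nrow(build_ddi_network(ds1)$edges), 1L)

  # self-declaration forms no edge
  ds2 <- ddi_dataset(
    data.frame(drug_id = "A1", name = "a", indication = ""),
    interactions = data.frame(drug_id = "A1", partner_id = "A1",
                              description = "self"))
  expect_message(net2 <- build_ddi_network(ds2, keep_isolated = TRUE),
                 "self-interaction")
  expect_equal(nrow(net2$edges), 0L)
  expect_equal(unname(ddi_degree(net2, "A1")), 0)  # isolated node
})

test_that("descriptions of merged declarations are concatenated in input order", {
  ds <- ddi_dataset(
    data.frame(drug_id = c("A1", "B1"), name = c("a", "b"),
               indication = c("", "")),
    interactions = data.frame(drug_id = c("A1", "B1"),
                              partner_id = c("B1", "A1"),
                              description = c("first wording", "second wording")))
  net <- build_ddi_network(ds)
  expect_equal(net$edges$description, "first wording | second wording")
})

test_that("handshake lemma holds on generated networks", {
  for (seed in 1:5) {
    net <- build_ddi_network(small_dataset(seed)$dataset)
    expect_equal(sum(ddi_degree(net)), 2 * nrow(net$edges))
  }
})

test_that("subnetwork keeps exactly edges touching the cohort", {
  ds <- ddi_dataset(
    data.frame(drug_id = c("A1", "B1", "C1"), name = c("a", "b", "c"),
               indication = c("", "", "")),
    interactions = data.frame(drug_id = c("A1", "B1", "C1"),
                              partner_id = c("B1", "C1", "A1"),
                              description = ""))
  net <- build_ddi_network(ds)
  sub <- extract_scz_subnetwork(net, "A1")
  expect_equal(nrow(sub$network$edges), 2L)    # AB and CA; BC removed
  expect_equal(sub$partition$intra_edges, 0L)
  expect_equal(sub$partition$inter_edges, 2L)

  sub2 <- extract_scz_subnetwork(net, c("A1", "B1"))
  expect_equal(sub2$partition$intra_edges, 1L) # both endpoints in cohort

  expect_warning(extract_scz_subnetwork(net, c("A1", "GHOST")), "GHOST")
})

test_that("subnetwork extraction is idempotent", {
  g <- small_dataset(9)
  net <- build_ddi_network(g$dataset)
  cohort <- intersect(g$truth$cohort$drug_id, igraph::V(net$graph)$name)
  s1 <- extract_scz_subnetwork(net, cohort)
  s2 <- extract_scz_subnetwork(s1$network, cohort)
  expect_equal(s2$network$edges, s1$network$edges)
  expect_equal(s2$partition, s1$partition)
})

test_that("reference-shaped fixture yields the expected partition and mean degree", {
  net <- build_ddi_network(shape_fixture_dataset())
  sub <- extract_scz_subnetwork(net, sprintf("C%02d", 1:28))
  p <- sub$partition
  expect_equal(p$n_scz_drugs, 28L)
  expect_equal(p$intra_edges, 43L)
  expect_equal(p$inter_edges, 948L)
  expect_length(p$partner_ids, 241L)
  expect_equal(round(partition_mean_degree(p), 2), 36.93)
})

test_that("partition mean degree agrees with the direct degree mean", {
  for (seed in c(2, 13)) {
    g <- small_dataset(seed)
    net <- build_ddi_network(g$dataset)
    cohort <- intersect(g$truth$cohort$drug_id, igraph::V(net$graph)$name)
    sub <- extract_scz_subnetwork(net, cohort)
    expect_equal(partition_mean_degree(sub),
                 degree_summary(sub$network, cohort)$mean)
  }
  # worked example: 5 cohort drugs, 2 intra + 6 inter edges
  expect_equal(partition_mean_degree(
    list(n_scz_drugs = 5, intra_edges = 2, inter_edges = 6)), 2.0)
  expect_equal(partition_mean_degree(
    list(n_scz_drugs = 7, intra_edges = 0, inter_edges = 0)), 0)
  expect_error(partition_mean_degree(
    list(n_scz_drugs = 0, intra_edges = 0, inter_edges = 0)), "empty")
})

test_that("degree lookup errors on unknown nodes, naming them", {
  net <- build_ddi_network(tiny_dataset())
  expect_error(ddi_degree(net, "NOPE"), "NOPE")
})
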