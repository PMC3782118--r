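test_that("TSV dialect preserves all record fields", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "drug_id\tname\tindication\tatc_codes\tpartners",
    "SYN00001\tAlphaxine\tFor the treatment of schizophrenia.\tN05AH02;A02BC01\tSYN00002|Increased sedation.",
    "SYN00002\tBetazole\tFor hypertension.\tC07AB02\tSYN00001|Increased sedation.",
    "SYN00003\tGammadol\tFor seasonal allergies.\t\t"), path)
  ds <- read_ddi_dataset(path, "tsv")
  expect_equal(nrow(ds$drugs), 3L)
  expect_equal(ds$atc_codes[["SYN00001"]], c("N05AH02", "A02BC01"))
  expect_equal(nrow(ds$interactions), 2L)
  rep <- validate_ddi_dataset(ds)
  expect_equal(rep$n_dangling_partners, 0L)
  expect_equal(rep$n_self_loops_removed, 0L)
})

test_that("write-then-read is the identity in all three dialects", {
  ds <- small_dataset(11)$dataset
  canon <- function(d) {
    int <- d$interactions[order(d$interactions$drug_id, d$interactions$partner_id,
                                d$interactions$description), ]
    rownames(int) <- NULL
    list(drugs = d$drugs, interactions = int, atc = d$atc_codes)
  }
  for (fmt in c("tsv", "json", "drugbank-xml-subset")) {
    path <- withr::local_tempfile()
    write_ddi_dataset(ds, path, fmt)
    back <- read_ddi_dataset(path, fmt)
    expect_equal(canon(back), canon(ds), info = fmt)
  }
})

test_that("ATC codes are normalized and invalid ones dropped with a warning", {
  expect_warning(
    ds <- ddi_dataset(
      data.frame(drug_id = "X1", name = "X", indication = ""),
      atc_codes = list(X1 = c("n05ah02", "N05A", "A02BC01"))),
    "invalid ATC")
  expect_equal(ds$atc_codes[["X1"]], c("N05AH02", "A02BC01"))
})

test_that("validation counts self-loops, duplicates and dangling refs without modifying the dataset", {
  ds <- ddi_dataset(
    data.frame(drug_id = c("A1", "B1"), name = c("a", "b"),
               indication = c("", "")),
    interactions = data.frame(
      drug_id = c("A1", "A1", "A1", "B1"),
      partner_id = c("A1", "B1", "B1", "Z9"),
      description = c("self", "first", "second wording", "dangling")))
  before <- ds
  rep <- validate_ddi_dataset(ds)
  expect_equal(rep$n_self_loops_removed, 1L)
  expect_equal(rep$n_duplicate_pairs_merged, 1L)
  expect_equal(rep$n_dangling_partners, 1L)
  expect_identical(ds, before)
  # idempotent
  expect_identical(validate_ddi_dataset(ds)[1:4], rep[1:4])
})

test_that("dataset constructor rejects structural violations", {
  drugs <- data.frame(drug_id = c("A1", "A1"), name = c("a", "b"),
                      indication = c("", ""))
  expect_error(ddi_dataset(drugs), "duplicate drug_id")
  expect_error(
    ddi_dataset(data.frame(drug_id = "A1", name = "a", indication = ""),
                interactions = data.frame(drug_id = "Q9", partner_id = "A1",
                                          description = "")),
    "unknown drug_id")
  expect_error(read_ddi_dataset("does-not-exist.tsv", "tsv"), "not found")
})

test_that("network exports: SIF lines, GraphML round trip, reference-shaped counts", {
  ds <- tiny_dataset()
  net <- build_ddi_network(ds)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_ddi_network(net, sif, "sif")
  expect_equal(readLines(sif), "SYN00001 pp SYN00002")

  big <- build_ddi_network(shape_fixture_dataset())
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_ddi_network(big, gml, "graphml", cohort = sprintf("C%02d", 1:28))
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 269)
  expect_equal(igraph::ecount(back), 991)
  expect_setequal(igraph::V(back)$name, igraph::V(big$graph)$name)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ddi_network(big, tsv, "tsv")
  edges <- utils::read.delim(tsv)
  expect_equal(nrow(edges), 991)
  expect_named(edges, c("drug_a", "drug_b", "description"))
})
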