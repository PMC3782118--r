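Package: sczddi
Title: Adverse Drug-Drug Interaction Networks for Antipsychotic Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization of adverse drug-drug interaction (DDI) networks
    for schizophrenia pharmacotherapy. Builds undirected adverse-DDI networks
    from drug-interaction datasets, selects an antipsychotic cohort by keyword
    and indication screening, stratifies drugs by the WHO Anatomical
    Therapeutic Chemical (ATC) hierarchy, compares degree distributions across
    ATC groups with the Wilcoxon rank-sum test under Bonferroni correction,
    and contrasts typical versus atypical antipsychotics by Fisher's exact
    test on interaction-category contingency tables. Includes a synthetic
    DrugBank-like data generator with planted enrichment effects so that every
    stage is testable without access to a proprietary database.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
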