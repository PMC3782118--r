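#' Compile cohort / other-N / non-N drug sets
#'
#' Given a network, the disease cohort, and a level-1 ATC group assignment
#' over the network's nodes, builds the standard comparison sets: the cohort
#' itself; other nervous-system drugs (`other_n`: drugs with an N code,
#' excluding the cohort); non-nervous-system drugs (`non_n`: annotated drugs
#' with no N code); and `all` network nodes (annotated or not). The first
#' three sets are pairwise disjoint; unannotated drugs appear only in `all`.
#'
#' @param network a `ddi_network`.
#' @param cohort character vector of cohort drug ids.
#' @param groups an [atc_groups()] assignment at level 1 computed over the
#'   network's nodes.
#' @return list of class `drug_sets` with character vectors `cohort`,
#'   `other_n`, `non_n`, `all`. A cohort member lacking any N code triggers
#'   a warning (it stays in the cohort set).
#' @export
compile_drug_sets <- function(network, cohort, groups) {
  stopifnot(inherits(network, "ddi_network"), inherits(groups, "atc_groups"))
  if (groups$level != 1L) stop("groups must be a level-1 assignment")
  nodes <- igraph::V(network$graph)$name
  cohort <- intersect(unique(as.character(cohort)), nodes)

  n_group <- intersect(groups$groups[["N"]], nodes)
  annotated <- intersect(unique(unlist(groups$groups, use.names = FALSE)), nodes)

  no_n <- setdiff(cohort, n_group)
  if (length(no_n) > 0L)
    warning("cohort member(s) without a nervous-system (N) ATC code: ",
            paste(no_n, collapse = ", "), call. = FALSE)

  structure(
    list(cohort = cohort,
         other_n = setdiff(n_group, cohort),
         non_n = setdiff(annotated, union(n_group, cohort)),
         all = nodes),
    class = "drug_sets"
  )
}

#' @export
print.drug_sets <- function(x, ...) {
  cat("Drug sets: cohort", length(x$cohort),
      "| other-N", length(x$other_n),
      "| non-N", length(x$non_n),
      "| all", length(x$all), "\n")
  invisible(x)
}

#' Compare one ATC group's degrees against each other group
#'
#' For a reference first-level ATC group (conventionally N, nervous system),
#' compares its degree distribution against every other group with the
#' rank-sum test and Bonferroni-adjusts using the total number of groups as
#' family size (14 when all anatomical main groups are present).
#'
#' @param network a `ddi_network`.
#' @param groups an [atc_groups()] assignment computed over network nodes.
#' @param reference class prefix of the reference group (default `"N"`).
#' @param alternative passed to [rank_sum_test()].
#' @return data frame of class `ddi_group_comparison`, one row per
#'   non-reference group: `set_a`, `set_b`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `p_raw`, `p_adjusted`, `family_size`, sorted by `p_raw`.
#'   Groups with fewer than 2 members get `p_raw = NA` and a warning.
#' @export
one_vs_each_group <- function(network, groups, reference = "N",
                              alternative = "two.sided") {
  stopifnot(inherits(network, "ddi_network"), inherits(groups, "atc_groups"))
  nodes <- igraph::V(network$graph)$name
  members <- lapply(groups$groups, intersect, nodes)
  members <- members[lengths(members) > 0L]
  if (!reference %in% names(members) || length(members[[reference]]) == 0L)
    stop("reference group ", sQuote(reference), " is empty")

  fam <- length(members)
  ref_deg <- ddi_degree(network, members[[reference]])
  others <- setdiff(names(members), reference)

  rows <- lapply(others, function(gr) {
    ids <- members[[gr]]
    deg <- ddi_degree(network, ids)
    if (length(ids) < 2L) {
      warning("group ", sQuote(gr), " has fewer than 2 members; p set to NA",
              call. = FALSE)
      p <- NA_real_
    } else {
      p <- rank_sum_test(ref_deg, deg, alternative = alternative)$p.value
    }
    data.frame(set_a = reference, set_b = gr,
               n_a = length(ref_deg), n_b = length(deg),
               mean_a = mean(ref_deg), mean_b = mean(deg),
               p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_raw, fam)
  out$family_size <- fam
  out <- out[order(out$p_raw), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ddi_group_comparison", "data.frame")
  out
}

#' @export
print.ddi_group_comparison <- function(x, digits = 3, ...) {
  cat("Degree comparison vs reference group", sQuote(x$set_a[1]),
      "(Bonferroni family size", x$family_size[1], ")\n")
  y <- as.data.frame(x)
  y$mean_a <- round(y$mean_a, 2); y$mean_b <- round(y$mean_b, 2)
  y$p_raw <- signif(y$p_raw, digits); y$p_adjusted <- signif(y$p_adjusted, digits)
  print(y, ...)
  invisible(x)
}
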