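#' Categorize a cohort subgroup's interactions by partner ATC class
#'
#' Walks the cohort-partner edges of a disease subnetwork whose cohort
#' endpoint lies in the given subgroup, and counts one link per *distinct*
#' ATC class prefix of the partner at the chosen level. A partner annotated
#' in two classes therefore contributes two classified links (multi-code
#' assignment), and the classified total is the sum of category counts, not
#' the number of distinct edges. Partners without any ATC code increment
#' `unclassified`.
#'
#' Intra-cohort edges are excluded by default (the typical-vs-atypical
#' contrast concerns interactions with non-cohort drugs); with
#' `include_intra = TRUE` they are categorized by the partner cohort drug's
#' own codes.
#'
#' @param subnetwork an [extract_scz_subnetwork()] result.
#' @param subgroup non-empty character vector of cohort drug ids (e.g. the
#'   typical drugs).
#' @param atc_codes named list drug_id -> ATC codes (as in a
#'   [ddi_dataset()]).
#' @param level ATC level, 1-5 (1 and 3 are the standard analyses).
#' @param include_intra also count intra-cohort edges.
#' @param name label for the subgroup (used in reports and direction tags).
#' @return An object of class `interaction_categories`: list with `level`,
#'   `name`, `counts` (named integer vector, class prefix -> link count),
#'   `classified_total`, `unclassified`.
#' @export
categorize_interactions <- function(subnetwork, subgroup, atc_codes,
                                    level = 1L, include_intra = FALSE,
                                    name = "subgroup") {
  stopifnot(inherits(subnetwork, "scz_subnetwork"))
  subgroup <- unique(as.character(subgroup))
  if (length(subgroup) == 0L) stop("subgroup must be non-empty")
  bad <- setdiff(subgroup, subnetwork$cohort)
  if (length(bad) > 0L)
    stop("subgroup member(s) outside the cohort: ", paste(bad, collapse = ", "))

  e <- subnetwork$network$edges
  cohort <- subnetwork$cohort
  a_c <- e$drug_a %in% cohort
  b_c <- e$drug_b %in% cohort
  intra <- a_c & b_c

  # inter edges whose cohort endpoint is in the subgroup; partner = other end
  inter_keep <- !intra & ((a_c & e$drug_a %in% subgroup) |
                            (b_c & e$drug_b %in% subgroup))
  partner <- ifelse(a_c[inter_keep], e$drug_b[inter_keep], e$drug_a[inter_keep])

  if (include_intra) {
    # categorize by the *other* cohort endpoint's codes; an edge inside the
    # subgroup is counted once from each side
    p2 <- c(e$drug_b[intra & e$drug_a %in% subgroup],
            e$drug_a[intra & e$drug_b %in% subgroup])
    partner <- c(partner, p2)
  }

  counts <- integer(0)
  unclassified <- 0L
  if (length(partner) > 0L) {
    prefs <- lapply(atc_codes[match(partner, names(atc_codes))],
                    function(codes) if (is.null(codes)) character() else
                      unique(atc_truncate(codes, level)))
    unclassified <- sum(lengths(prefs) == 0L)
    pref <- unlist(prefs, use.names = FALSE)
    if (length(pref) > 0L) {
      tab <- table(pref)
      counts <- stats::setNames(as.integer(tab), names(tab))
      counts <- counts[order(names(counts))]
    }
  }
  structure(
    list(level = as.integer(level), name = name, counts = counts,
         classified_total = sum(counts), unclassified = unclassified),
    class = "interaction_categories"
  )
}

#' @export
print.interaction_categories <- function(x, ...) {
  cat("Interaction categories (ATC level ", x$level, ") for ", x$name, "\n",
      sep = "")
  cat("  categories:      ", length(x$counts), "\n")
  cat("  classified links:", x$classified_total, "\n")
  cat("  unclassified:    ", x$unclassified, "\n")
  invisible(x)
}

#' Compare interaction-category profiles of two cohort subgroups
#'
#' For every category observed in either subgroup, builds the 2x2 table
#' `n, N-n, r, R-r` (category links vs all classified links, per subgroup)
#' and applies the two-sided [fisher_exact_2x2()] test. The Bonferroni family
#' size is the number of emitted rows.
#'
#' @param counts_a,counts_b [categorize_interactions()] results at the same
#'   level (conventionally typical and atypical).
#' @param correction `"bonferroni"` or `"none"`.
#' @param labels optional named character vector, category prefix -> display
#'   label; level-1 letters are labeled automatically.
#' @return data frame of class `ddi_enrichment`, sorted by `p_raw`, with
#'   columns `category`, `label`, `n`, `N`, `pct_a`, `r`, `R`, `pct_b`,
#'   `p_raw`, `p_adjusted`, `direction`. Direction compares the unrounded
#'   proportions `n/N` and `r/R`; tags use the subgroup names (e.g.
#'   `"typical-enriched"`).
#' @export
compare_subgroups <- function(counts_a, counts_b,
                              correction = c("bonferroni", "none"),
                              labels = NULL) {
  stopifnot(inherits(counts_a, "interaction_categories"),
            inherits(counts_b, "interaction_categories"))
  correction <- match.arg(correction)
  if (counts_a$level != counts_b$level)
    stop("subgroup category counts computed at different ATC levels")

  cats <- sort(union(names(counts_a$counts), names(counts_b$counts)))
  n <- ifelse(cats %in% names(counts_a$counts), counts_a$counts[cats], 0L)
  r <- ifelse(cats %in% names(counts_b$counts), counts_b$counts[cats], 0L)
  N <- counts_a$classified_total
  R <- counts_b$classified_total

  if (length(cats) == 0L) {
    out <- data.frame(category = character(), label = character(),
                      n = integer(), N = integer(), pct_a = numeric(),
                      r = integer(), R = integer(), pct_b = numeric(),
                      p_raw = numeric(), p_adjusted = numeric(),
                      direction = character())
  } else {
    p <- fisher_exact_2x2(n, N, r, R)
    prop_a <- n / N
    prop_b <- r / R
    direction <- ifelse(prop_a > prop_b, paste0(counts_a$name, "-enriched"),
                        ifelse(prop_b > prop_a,
                               paste0(counts_b$name, "-enriched"), "none"))
    lab <- if (counts_a$level == 1L) unname(ATC_LEVEL1_LABELS[cats]) else
      rep(NA_character_, length(cats))
    if (!is.null(labels)) {
      hit <- cats %in% names(labels)
      lab[hit] <- unname(labels[cats[hit]])
    }
    out <- data.frame(category = cats, label = lab,
                      n = as.integer(n), N = N, pct_a = 100 * prop_a,
                      r = as.integer(r), R = R, pct_b = 100 * prop_b,
                      p_raw = p,
                      p_adjusted = if (correction == "bonferroni")
                        bonferroni(p, length(cats)) else p,
                      direction = direction)
    out <- out[order(out$p_raw, out$category), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "subgroups") <- c(counts_a$name, counts_b$name)
  attr(out, "level") <- counts_a$level
  attr(out, "correction") <- correction
  class(out) <- c("ddi_enrichment", "data.frame")
  out
}

#' @export
print.ddi_enrichment <- function(x, digits = 3, ...) {
  sg <- attr(x, "subgroups")
  cat("Interaction-category enrichment (ATC level ", attr(x, "level"), "): ",
      sg[1], " vs ", sg[2], "\n", sep = "")
  y <- as.data.frame(x)
  y$pct_a <- round_half_up(y$pct_a, 2)
  y$pct_b <- round_half_up(y$pct_b, 2)
  y$p_raw <- signif(y$p_raw, digits)
  y$p_adjusted <- signif(y$p_adjusted, digits)
  print(y, ...)
  invisible(x)
}

#' Common and subgroup-specific categories
#'
#' Partitions the categories observed (count > 0) in either subgroup into
#' those present in both and those specific to one.
#'
#' @param counts_a,counts_b [categorize_interactions()] results at the same
#'   level.
#' @return list with character vectors `common`, `specific_a`, `specific_b`.
#' @export
category_overlap <- function(counts_a, counts_b) {
  stopifnot(inherits(counts_a, "interaction_categories"),
            inherits(counts_b, "interaction_categories"))
  if (counts_a$level != counts_b$level)
    stop("subgroup category counts computed at different ATC levels")
  a <- names(counts_a$counts)[counts_a$counts > 0L]
  b <- names(counts_b$counts)[counts_b$counts > 0L]
  list(common = sort(intersect(a, b)),
       specific_a = sort(setdiff(a, b)),
       specific_b = sort(setdiff(b, a)))
}

# Report convention: percentages to 2 decimals, round half up.
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}
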