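#' Default schizophrenia screening keywords
#'
#' The inflected forms used to screen drug records for schizophrenia
#' relevance. Matching is case-insensitive plain substring, so
#' "schizophrenia" also hits "schizophrenias".
#'
#' @return character vector of lowercase keywords.
#' @export
scz_keywords <- function() {
  c("schizophrenia", "schizophrenias", "schizophrenic", "schizophrenics",
    "schizotypy", "schizotypal")
}

#' Screen drugs by keyword across all text fields
#'
#' Returns drugs where any keyword occurs case-insensitively as a substring
#' in the drug's name, indication, or any of its declared interaction
#' descriptions. No word boundaries and no stemming: the keyword list is
#' expected to enumerate inflections.
#'
#' @param dataset a [ddi_dataset()].
#' @param keywords non-empty character vector.
#' @return character vector of matching drug ids (dataset order).
#' @export
keyword_screen <- function(dataset, keywords = scz_keywords()) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  keywords <- tolower(as.character(keywords))
  if (length(keywords) == 0L) stop("keywords must be non-empty")

  hit_text <- function(text) {
    hits <- rep(FALSE, length(text))
    text <- tolower(text)
    for (kw in keywords) hits <- hits | grepl(kw, text, fixed = TRUE)
    hits
  }
  hits <- hit_text(dataset$drugs$name) | hit_text(dataset$drugs$indication)
  desc_hit <- hit_text(dataset$interactions$description)
  hits <- hits | dataset$drugs$drug_id %in%
    unique(dataset$interactions$drug_id[desc_hit])
  dataset$drugs$drug_id[hits]
}

#' Filter screened candidates by the indication field
#'
#' Keeps only candidates whose indication text itself contains one of the
#' keywords: the indication field names the diseases a drug treats, so this
#' distinguishes drugs *for* the disease from drugs merely mentioning it.
#'
#' @param dataset a [ddi_dataset()].
#' @param candidates character vector of drug ids (subset of the dataset).
#' @param keywords character vector of keywords.
#' @return character vector: the candidates with an indication hit.
#' @export
indication_filter <- function(dataset, candidates, keywords = scz_keywords()) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  candidates <- as.character(candidates)
  if (any(!candidates %in% dataset$drugs$drug_id))
    stop("candidates outside the dataset")
  keywords <- tolower(as.character(keywords))
  ind <- tolower(dataset$drugs$indication[
    match(candidates, dataset$drugs$drug_id)])
  hits <- rep(FALSE, length(candidates))
  for (kw in keywords) hits <- hits | grepl(kw, ind, fixed = TRUE)
  candidates[hits]
}

#' Define a disease-drug cohort
#'
#' Bundles screening keywords, manual include/exclude overrides (the
#' reproducible stand-in for manual curation), and a typical/atypical
#' typology map.
#'
#' @param keywords character vector of screening keywords.
#' @param include,exclude character vectors of drug ids forced in or out of
#'   the cohort; must be disjoint.
#' @param typology named character vector drug_id -> "typical"/"atypical".
#' @return An object of class `cohort_definition`.
#' @export
cohort_definition <- function(keywords = scz_keywords(),
                              include = character(),
                              exclude = character(),
                              typology = character()) {
  include <- unique(as.character(include))
  exclude <- unique(as.character(exclude))
  both <- intersect(include, exclude)
  if (length(both) > 0L)
    stop("include and exclude overlap: ", paste(both, collapse = ", "))
  if (length(typology) > 0L) {
    typology <- stats::setNames(as.character(typology), names(typology))
    bad <- setdiff(unique(typology), c("typical", "atypical"))
    if (length(bad) > 0L)
      stop("typology values must be 'typical' or 'atypical', got: ",
           paste(bad, collapse = ", "))
  }
  structure(
    list(keywords = tolower(as.character(keywords)),
         include = include, exclude = exclude, typology = typology),
    class = "cohort_definition"
  )
}

#' Resolve the final cohort from screening results and overrides
#'
#' The final cohort is `(indicated` \eqn{\cup} `include) \\ exclude`. Every
#' final member and every applied exclusion gets an audit tag:
#' `keyword+indication`, `manual-include`, or `manual-exclude`.
#'
#' @param screened drug ids hit by [keyword_screen()].
#' @param indicated drug ids retained by [indication_filter()].
#' @param definition a [cohort_definition()].
#' @return An object of class `cohort_result`: list with `screened`,
#'   `indicated`, `final`, and data frame `audit` (`drug_id`, `tag`).
#' @export
resolve_cohort <- function(screened, indicated, definition = cohort_definition()) {
  stopifnot(inherits(definition, "cohort_definition"))
  screened <- unique(as.character(screened))
  indicated <- unique(as.character(indicated))

  noop_excl <- setdiff(definition$exclude, union(indicated, definition$include))
  if (length(noop_excl) > 0L)
    warning("exclude override(s) not in the candidate cohort (no effect): ",
            paste(noop_excl, collapse = ", "), call. = FALSE)

  final <- setdiff(union(indicated, definition$include), definition$exclude)
  applied_excl <- intersect(definition$exclude, union(indicated, definition$include))

  tag <- ifelse(final %in% indicated, "keyword+indication", "manual-include")
  audit <- data.frame(
    drug_id = c(final, applied_excl),
    tag = c(tag, rep("manual-exclude", length(applied_excl)))
  )
  structure(
    list(screened = screened, indicated = indicated, final = final,
         audit = audit),
    class = "cohort_result"
  )
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort selection\n")
  cat("  keyword hits (any field):", length(x$screened), "\n")
  cat("  indication hits:         ", length(x$indicated), "\n")
  cat("  final cohort:            ", length(x$final), "\n")
  n_excl <- sum(x$audit$tag == "manual-exclude")
  if (n_excl > 0L) cat("  manual exclusions:       ", n_excl, "\n")
  invisible(x)
}

#' Attach typical/atypical labels to a cohort
#'
#' Restricts a typology map to the cohort. Labels for non-cohort drugs are
#' ignored with a warning; unlabeled cohort members are recorded in the
#' `unlabeled` attribute and cause a hard error when `require_complete` is
#' set (as typology-stratified analyses do).
#'
#' @param cohort character vector of drug ids.
#' @param labels named character vector drug_id -> "typical"/"atypical".
#' @param require_complete error if any cohort member is unlabeled.
#' @return named character vector over the labeled cohort members, with
#'   attribute `unlabeled`.
#' @export
label_typology <- function(cohort, labels, require_complete = FALSE) {
  cohort <- unique(as.character(cohort))
  bad <- setdiff(unique(labels), c("typical", "atypical"))
  if (length(bad) > 0L)
    stop("typology values must be 'typical' or 'atypical', got: ",
         paste(bad, collapse = ", "))
  extra <- setdiff(names(labels), cohort)
  if (length(extra) > 0L)
    warning("typology label(s) for non-cohort drug(s) ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  out <- labels[intersect(cohort, names(labels))]
  unlabeled <- setdiff(cohort, names(out))
  if (require_complete && length(unlabeled) > 0L)
    stop("cohort member(s) without typical/atypical label: ",
         paste(unlabeled, collapse = ", "))
  attr(out, "unlabeled") <- unlabeled
  out
}
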