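#' Construct a drug-interaction dataset
#'
#' A `ddi_dataset` holds one record per drug (identifier, name, free-text
#' indication), the drug's ATC codes, and its declared adverse-interaction
#' partners with free-text descriptions. Partner declarations are stored as
#' recorded (possibly one-sided); [build_ddi_network()] merges them into
#' undirected edges.
#'
#' @param drugs data frame with columns `drug_id`, `name`, `indication`
#'   (character). `drug_id` must be non-empty and unique.
#' @param interactions data frame with columns `drug_id`, `partner_id`,
#'   `description`, one row per declared interaction, or `NULL` for none.
#' @param atc_codes named list mapping `drug_id` to a character vector of
#'   7-character ATC codes. Codes are upper-cased and syntax-checked;
#'   invalid codes are dropped with a warning. Drugs absent from the list
#'   carry no annotation.
#' @param provenance free-text metadata (source name, version, seed).
#'
#' @return An object of class `ddi_dataset`: a list with elements `drugs`,
#'   `interactions`, `atc_codes`, `provenance`.
#' @seealso [read_ddi_dataset()], [validate_ddi_dataset()],
#'   [build_ddi_network()]
#' @export
ddi_dataset <- function(drugs, interactions = NULL, atc_codes = list(),
                        provenance = "") {
  stopifnot(is.data.frame(drugs))
  need <- c("drug_id", "name", "indication")
  miss <- setdiff(need, names(drugs))
  if (length(miss) > 0L)
    stop("drugs is missing columns: ", paste(miss, collapse = ", "))
  drugs <- as.data.frame(drugs)[need]
  for (col in need) drugs[[col]] <- as.character(drugs[[col]])
  if (anyNA(drugs$drug_id) || any(!nzchar(drugs$drug_id)))
    stop("drug_id must be non-empty")
  if (anyDuplicated(drugs$drug_id))
    stop("duplicate drug_id: ",
         paste(unique(drugs$drug_id[duplicated(drugs$drug_id)]), collapse = ", "))

  if (is.null(interactions)) {
    interactions <- data.frame(drug_id = character(), partner_id = character(),
                               description = character())
  }
  stopifnot(is.data.frame(interactions))
  ineed <- c("drug_id", "partner_id", "description")
  imiss <- setdiff(ineed, names(interactions))
  if (length(imiss) > 0L)
    stop("interactions is missing columns: ", paste(imiss, collapse = ", "))
  interactions <- as.data.frame(interactions)[ineed]
  for (col in ineed) interactions[[col]] <- as.character(interactions[[col]])
  if (any(!interactions$drug_id %in% drugs$drug_id))
    stop("interactions declared by unknown drug_id")
  rownames(drugs) <- NULL
  rownames(interactions) <- NULL

  atc_codes <- atc_codes[lengths(atc_codes) > 0L]
  if (length(atc_codes) > 0L) {
    if (is.null(names(atc_codes)) || any(!nzchar(names(atc_codes))))
      stop("atc_codes must be a named list keyed by drug_id")
    unknown <- setdiff(names(atc_codes), drugs$drug_id)
    if (length(unknown) > 0L)
      stop("atc_codes given for unknown drugs: ", paste(unknown, collapse = ", "))
    atc_codes <- lapply(atc_codes, clean_atc)
    atc_codes <- atc_codes[lengths(atc_codes) > 0L]
    atc_codes <- atc_codes[order(match(names(atc_codes), drugs$drug_id))]
  }

  structure(
    list(drugs = drugs, interactions = interactions,
         atc_codes = atc_codes, provenance = as.character(provenance)[1L]),
    class = "ddi_dataset"
  )
}

# Upper-case, deduplicate and syntax-check a vector of ATC codes; invalid
# entries are dropped with one warning naming them.
clean_atc <- function(codes) {
  codes <- unique(toupper(as.character(codes)))
  codes <- codes[nzchar(codes)]
  bad <- codes[!is_atc(codes)]
  if (length(bad) > 0L)
    warning("dropping invalid ATC code(s): ", paste(bad, collapse = ", "),
            call. = FALSE)
  codes[is_atc(codes)]
}

#' @export
print.ddi_dataset <- function(x, ...) {
  cat("Drug-interaction dataset\n")
  cat("  drugs:                 ", nrow(x$drugs), "\n")
  cat("  interaction records:   ", nrow(x$interactions), "\n")
  cat("  drugs with ATC codes:  ", length(x$atc_codes), "\n")
  if (nzchar(x$provenance)) cat("  provenance:            ", x$provenance, "\n")
  invisible(x)
}

#' Validate a drug-interaction dataset
#'
#' Counts dangling partner references (partners not resolving to a record),
#' self-interaction declarations, and duplicate declarations of the same
#' unordered drug pair. Validation never fails on content and leaves the
#' dataset unmodified; [build_ddi_network()] is where self-loops and dangling
#' partners are actually dropped.
#'
#' @param dataset a [ddi_dataset()].
#' @return An object of class `ddi_validation`: a list with counts
#'   `n_records`, `n_dangling_partners`, `n_self_loops_removed`,
#'   `n_duplicate_pairs_merged` and a character vector `messages`.
#' @export
validate_ddi_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  int <- dataset$interactions
  msgs <- character()

  dangling <- !(int$partner_id %in% dataset$drugs$drug_id)
  if (any(dangling))
    msgs <- c(msgs, paste0(sum(dangling), " dangling partner reference(s): ",
                           paste(utils::head(unique(int$partner_id[dangling]), 5L),
                                 collapse = ", ")))

  self <- int$drug_id == int$partner_id
  if (any(self))
    msgs <- c(msgs, paste0(sum(self), " self-interaction declaration(s)"))

  ok <- !dangling & !self
  key <- pair_key(int$drug_id[ok], int$partner_id[ok])
  n_dup <- if (length(key) > 0L) sum(table(key) - 1L) else 0L
  if (n_dup > 0L)
    msgs <- c(msgs, paste0(n_dup, " duplicate pair declaration(s) merged on ",
                           "network construction"))

  structure(
    list(n_records = nrow(dataset$drugs),
         n_dangling_partners = sum(dangling),
         n_self_loops_removed = sum(self),
         n_duplicate_pairs_merged = as.integer(n_dup),
         messages = msgs),
    class = "ddi_validation"
  )
}

#' @export
print.ddi_validation <- function(x, ...) {
  cat("Dataset validation\n")
  cat("  records:               ", x$n_records, "\n")
  cat("  dangling partners:     ", x$n_dangling_partners, "\n")
  cat("  self-loops (dropped):  ", x$n_self_loops_removed, "\n")
  cat("  duplicate pairs merged:", x$n_duplicate_pairs_merged, "\n")
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

# Canonical unordered pair key, sorted lexicographically for determinism.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
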