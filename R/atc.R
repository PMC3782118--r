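#' ATC classification utilities
#'
#' The WHO Anatomical Therapeutic Chemical (ATC) system assigns drugs
#' 7-character codes over five nested levels, e.g. `N05AH02`: `N` (nervous
#' system, level 1), `N05` (psycholeptics, level 2), `N05A` (antipsychotics,
#' level 3), `N05AH` (level 4) and the full code at level 5. Prefix lengths
#' by level are 1, 3, 4, 5 and 7 characters.
#'
#' @name atc
NULL

# The 14 anatomical main groups of the first level.
ATC_LEVEL1 <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R",
                "S", "V")

ATC_LEVEL1_LABELS <- c(
  A = "Alimentary tract and metabolism",
  B = "Blood and blood forming organs",
  C = "Cardiovascular system",
  D = "Dermatologicals",
  G = "Genitourinary system and sex hormones",
  H = "Systemic hormonal preparations, excluding sex hormones and insulins",
  J = "Antiinfectives for systemic use",
  L = "Antineoplastic and immunomodulating agents",
  M = "Musculoskeletal system",
  N = "Nervous system",
  P = "Antiparasitic products, insecticides, and repellents",
  R = "Respiratory system",
  S = "Sensory organs",
  V = "Various"
)

.ATC_PREFIX_LEN <- c(1L, 3L, 4L, 5L, 7L)

#' Test whether strings are syntactically valid ATC codes
#'
#' @param x character vector.
#' @return logical vector: `TRUE` where `x` matches the 7-character pattern
#'   letter, digit, digit, letter, letter, digit, digit (case-insensitive).
#' @export
is_atc <- function(x) {
  grepl("^[A-Za-z][0-9]{2}[A-Za-z]{2}[0-9]{2}$", x)
}

#' Parse and normalize ATC codes
#'
#' Upper-cases and validates 7-character ATC codes. Invalid input raises an
#' error naming the offending text.
#'
#' @param x character vector of candidate codes.
#' @return character vector of normalized codes.
#' @examples
#' parse_atc("n05ah02")  # "N05AH02"
#' @export
parse_atc <- function(x) {
  x <- toupper(as.character(x))
  bad <- x[!is_atc(x)]
  if (length(bad) > 0L)
    stop("invalid ATC code(s): ", paste(sQuote(bad), collapse = ", "))
  x
}

#' Truncate ATC codes to a hierarchy level
#'
#' @param code character vector of valid 7-character ATC codes.
#' @param level integer in 1..5.
#' @return character vector of class prefixes of length 1, 3, 4, 5 or 7.
#' @examples
#' atc_truncate("N05AH02", 1)  # "N"
#' atc_truncate("N05AH02", 3)  # "N05A"
#' @export
atc_truncate <- function(code, level) {
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L || level > 5L)
    stop("level must be a single integer in 1..5")
  code <- parse_atc(code)
  substr(code, 1L, .ATC_PREFIX_LEN[level])
}

#' Group drugs by ATC class at a hierarchy level
#'
#' Every annotated drug appears under each *distinct* class prefix of its
#' codes at the chosen level (a drug with two codes sharing a prefix counts
#' once in that class); drugs with no codes go to `unannotated`.
#'
#' @param atc_codes named list mapping drug_id to character vectors of ATC
#'   codes (as stored in a [ddi_dataset()]).
#' @param level integer in 1..5.
#' @param drug_ids character vector of all drugs to cover; defaults to
#'   `names(atc_codes)`. Drugs in `drug_ids` without codes are reported as
#'   unannotated.
#' @return An object of class `atc_groups`: list with `level`, `groups`
#'   (named list, class prefix -> character vector of drug ids) and
#'   `unannotated` (character vector). At level 1 a prefix outside the 14
#'   anatomical main groups triggers a validation warning.
#' @export
atc_groups <- function(atc_codes, level = 1L, drug_ids = names(atc_codes)) {
  level <- as.integer(level)
  if (length(level) != 1L || is.na(level) || level < 1L || level > 5L)
    stop("level must be a single integer in 1..5")
  drug_ids <- unique(as.character(drug_ids))
  atc_codes <- atc_codes[intersect(names(atc_codes), drug_ids)]
  atc_codes <- atc_codes[lengths(atc_codes) > 0L]

  groups <- list()
  if (length(atc_codes) > 0L) {
    prefixes <- lapply(atc_codes, function(codes)
      unique(atc_truncate(codes, level)))
    id_rep <- rep(names(prefixes), lengths(prefixes))
    pref <- unlist(prefixes, use.names = FALSE)
    groups <- split(id_rep, pref)
    groups <- groups[order(names(groups))]
  }
  if (level == 1L) {
    alien <- setdiff(names(groups), ATC_LEVEL1)
    if (length(alien) > 0L)
      warning("first-level prefix outside the 14 anatomical main groups: ",
              paste(alien, collapse = ", "), call. = FALSE)
  }
  structure(
    list(level = level, groups = groups,
         unannotated = setdiff(drug_ids, names(atc_codes))),
    class = "atc_groups"
  )
}

#' @export
print.atc_groups <- function(x, ...) {
  cat("ATC group assignment (level ", x$level, ")\n", sep = "")
  cat("  groups:      ", length(x$groups), "\n")
  cat("  annotated:   ",
      length(unique(unlist(x$groups, use.names = FALSE))), "\n")
  cat("  unannotated: ", length(x$unannotated), "\n")
  invisible(x)
}
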