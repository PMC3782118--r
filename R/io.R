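#' Read a drug-interaction dataset
#'
#' Three interchange dialects are supported:
#' \describe{
#'   \item{`tsv`}{one row per drug; columns `drug_id`, `name`, `indication`,
#'     `atc_codes` (semicolon-separated), `partners` (semicolon-separated
#'     `partner_id|description` tokens); UTF-8 with a header row. Field text
#'     must not contain tabs, semicolons or pipes.}
#'   \item{`json`}{array of record objects with the same field names;
#'     `atc_codes` an array of strings, `partners` an array of
#'     `{partner_id, description}` objects.}
#'   \item{`drugbank-xml-subset`}{a minimal DrugBank-like XML layout reading
#'     only `drugbank-id`, `name`, `indication`, `atc-codes/atc-code/@code`
#'     and `drug-interactions/drug-interaction` elements; everything else is
#'     ignored, so a real export can be used but is never required.}
#' }
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"json"`, `"drugbank-xml-subset"`.
#' @return a [ddi_dataset()].
#' @export
read_ddi_dataset <- function(path, format = c("tsv", "json",
                                              "drugbank-xml-subset")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "tsv" = read_dataset_tsv(path),
         "json" = read_dataset_json(path),
         "drugbank-xml-subset" = read_dataset_xml(path))
}

#' Write a drug-interaction dataset
#'
#' Inverse of [read_ddi_dataset()]; `read(write(dataset))` reproduces the
#' dataset field-for-field in all three dialects.
#'
#' @param dataset a [ddi_dataset()].
#' @param path file path.
#' @param format one of `"tsv"`, `"json"`, `"drugbank-xml-subset"`.
#' @export
write_ddi_dataset <- function(dataset, path,
                              format = c("tsv", "json",
                                         "drugbank-xml-subset")) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  format <- match.arg(format)
  switch(format,
         "tsv" = write_dataset_tsv(dataset, path),
         "json" = write_dataset_json(dataset, path),
         "drugbank-xml-subset" = write_dataset_xml(dataset, path))
  invisible(path)
}

split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1L]]
}

read_dataset_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          check.names = FALSE, na.strings = NULL,
                          fileEncoding = "UTF-8")
  need <- c("drug_id", "name", "indication", "atc_codes", "partners")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("malformed TSV (missing column(s): ", paste(miss, collapse = ", "),
         ") in ", path)
  atc <- lapply(df$atc_codes, split_tokens)
  names(atc) <- df$drug_id
  rows <- lapply(seq_len(nrow(df)), function(i) {
    toks <- split_tokens(df$partners[i])
    if (length(toks) == 0L) return(NULL)
    bad <- !grepl("|", toks, fixed = TRUE)
    if (any(bad))
      stop("malformed partner token(s) for drug ", df$drug_id[i], ": ",
           paste(toks[bad], collapse = ", "))
    data.frame(drug_id = df$drug_id[i],
               partner_id = sub("\\|.*$", "", toks),
               description = sub("^[^|]*\\|", "", toks))
  })
  interactions <- do.call(rbind, rows)
  ddi_dataset(df[c("drug_id", "name", "indication")], interactions,
              atc_codes = atc, provenance = paste0("tsv:", basename(path)))
}

write_dataset_tsv <- function(dataset, path) {
  drugs <- dataset$drugs
  atc <- vapply(drugs$drug_id, function(id) {
    cs <- dataset$atc_codes[[id]]
    if (is.null(cs)) "" else paste(cs, collapse = ";")
  }, "")
  int <- dataset$interactions
  parts <- vapply(drugs$drug_id, function(id) {
    rows <- int[int$drug_id == id, , drop = FALSE]
    if (nrow(rows) == 0L) return("")
    paste(paste0(rows$partner_id, "|", rows$description), collapse = ";")
  }, "")
  out <- data.frame(drug_id = drugs$drug_id, name = drugs$name,
                    indication = drugs$indication, atc_codes = unname(atc),
                    partners = unname(parts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_dataset_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(recs)) stop("malformed JSON dataset in ", path)
  get_chr <- function(x, f) {
    v <- x[[f]]
    if (is.null(v)) "" else as.character(v)
  }
  drugs <- data.frame(
    drug_id = vapply(recs, get_chr, "", "drug_id"),
    name = vapply(recs, get_chr, "", "name"),
    indication = vapply(recs, get_chr, "", "indication"))
  atc <- lapply(recs, function(x)
    vapply(x$atc_codes, as.character, ""))
  names(atc) <- drugs$drug_id
  rows <- lapply(recs, function(x) {
    ps <- x$partners
    if (is.null(ps) || length(ps) == 0L) return(NULL)
    data.frame(drug_id = as.character(x$drug_id),
               partner_id = vapply(ps, get_chr, "", "partner_id"),
               description = vapply(ps, get_chr, "", "description"))
  })
  ddi_dataset(drugs, do.call(rbind, rows), atc_codes = atc,
              provenance = paste0("json:", basename(path)))
}

write_dataset_json <- function(dataset, path) {
  int <- dataset$interactions
  recs <- lapply(seq_len(nrow(dataset$drugs)), function(i) {
    id <- dataset$drugs$drug_id[i]
    rows <- int[int$drug_id == id, , drop = FALSE]
    list(drug_id = id,
         name = dataset$drugs$name[i],
         indication = dataset$drugs$indication[i],
         atc_codes = as.list(dataset$atc_codes[[id]] %||% character()),
         partners = if (nrow(rows) == 0L) list() else
           lapply(seq_len(nrow(rows)), function(j)
             list(partner_id = rows$partner_id[j],
                  description = rows$description[j])))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_dataset_xml <- function(path) {
  doc <- xml2::read_xml(path)
  drugs_nodes <- xml2::xml_find_all(doc, ".//drug[drugbank-id]")
  txt <- function(node, xp) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xp))
    if (is.na(v)) "" else v
  }
  ids <- vapply(drugs_nodes, txt, "", "./drugbank-id")
  drugs <- data.frame(
    drug_id = ids,
    name = vapply(drugs_nodes, txt, "", "./name"),
    indication = vapply(drugs_nodes, txt, "", "./indication"))
  atc <- lapply(drugs_nodes, function(n)
    xml2::xml_attr(xml2::xml_find_all(n, "./atc-codes/atc-code"), "code"))
  names(atc) <- ids
  rows <- lapply(seq_along(drugs_nodes), function(i) {
    ints <- xml2::xml_find_all(drugs_nodes[[i]],
                               "./drug-interactions/drug-interaction")
    if (length(ints) == 0L) return(NULL)
    data.frame(drug_id = ids[i],
               partner_id = vapply(ints, txt, "", "./drugbank-id"),
               description = vapply(ints, txt, "", "./description"))
  })
  ddi_dataset(drugs, do.call(rbind, rows), atc_codes = atc,
              provenance = paste0("drugbank-xml-subset:", basename(path)))
}

write_dataset_xml <- function(dataset, path) {
  root <- xml2::xml_new_root("drugbank")
  int <- dataset$interactions
  for (i in seq_len(nrow(dataset$drugs))) {
    id <- dataset$drugs$drug_id[i]
    drug <- xml2::xml_add_child(root, "drug")
    xml2::xml_add_child(drug, "drugbank-id", id)
    xml2::xml_add_child(drug, "name", dataset$drugs$name[i])
    xml2::xml_add_child(drug, "indication", dataset$drugs$indication[i])
    atc_node <- xml2::xml_add_child(drug, "atc-codes")
    for (code in dataset$atc_codes[[id]] %||% character())
      xml2::xml_add_child(atc_node, "atc-code", code = code)
    ints_node <- xml2::xml_add_child(drug, "drug-interactions")
    rows <- int[int$drug_id == id, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      di <- xml2::xml_add_child(ints_node, "drug-interaction")
      xml2::xml_add_child(di, "drugbank-id", rows$partner_id[j])
      xml2::xml_add_child(di, "description", rows$description[j])
    }
  }
  xml2::write_xml(root, path)
}

#' Export a DDI network
#'
#' Writes Cytoscape-readable network files. The `graphml` dialect carries
#' node attributes (`scz` flag, `typology`, first-level ATC letters,
#' `degree`); `sif` uses interaction type `pp`; `tsv` is an edge list with
#' columns `drug_a`, `drug_b`, `description`.
#'
#' @param network a `ddi_network` (non-empty).
#' @param path file path.
#' @param format one of `"graphml"`, `"sif"`, `"tsv"`.
#' @param cohort optional cohort ids: sets the `scz` node attribute.
#' @param typology optional named vector drug_id -> typology.
#' @param atc_codes optional named list drug_id -> ATC codes; first-level
#'   letters are exported semicolon-separated.
#' @export
write_ddi_network <- function(network, path,
                              format = c("graphml", "sif", "tsv"),
                              cohort = NULL, typology = NULL,
                              atc_codes = NULL) {
  stopifnot(inherits(network, "ddi_network"))
  format <- match.arg(format)
  if (igraph::vcount(network$graph) == 0L) stop("network is empty")

  if (format == "sif") {
    lines <- paste(network$edges$drug_a, "pp", network$edges$drug_b)
    writeLines(lines, path)
    return(invisible(path))
  }
  if (format == "tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  g <- network$graph
  nodes <- igraph::V(g)$name
  igraph::V(g)$scz <- as.integer(nodes %in% (cohort %||% character()))
  tp <- rep("", length(nodes))
  if (!is.null(typology)) {
    hit <- nodes %in% names(typology)
    tp[hit] <- unname(typology[nodes[hit]])
  }
  igraph::V(g)$typology <- tp
  l1 <- rep("", length(nodes))
  if (!is.null(atc_codes)) {
    l1 <- vapply(nodes, function(id) {
      cs <- atc_codes[[id]]
      if (is.null(cs)) "" else
        paste(sort(unique(substr(cs, 1L, 1L))), collapse = ";")
    }, "")
  }
  igraph::V(g)$atc_level1 <- unname(l1)
  igraph::V(g)$degree <- unname(igraph::degree(g))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
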