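#' Build the undirected adverse-DDI network
#'
#' Forms one undirected edge per unordered drug pair declared by either
#' endpoint: interaction direction is ignored, so a one-sided declaration
#' suffices. Self-interaction declarations and declarations naming a partner
#' without a record (dangling) are dropped; descriptions of duplicate or
#' reciprocal declarations are merged in input order.
#'
#' @param dataset a [ddi_dataset()].
#' @param keep_isolated also include drugs that take part in no interaction
#'   as isolated nodes (default `FALSE`: the network covers drugs in DDIs).
#' @return An object of class `ddi_network`: list with `graph` (an
#'   undirected [igraph][igraph::graph_from_data_frame] graph), and `edges`
#'   (data frame `drug_a`, `drug_b`, `description`, keyed by sorted pair).
#' @export
build_ddi_network <- function(dataset, keep_isolated = FALSE) {
  stopifnot(inherits(dataset, "ddi_dataset"))
  int <- dataset$interactions

  dangling <- !(int$partner_id %in% dataset$drugs$drug_id)
  if (any(dangling))
    message("dropping ", sum(dangling), " declaration(s) with dangling partners")
  self <- int$drug_id == int$partner_id
  if (any(self))
    message("dropping ", sum(self), " self-interaction declaration(s)")
  int <- int[!dangling & !self, , drop = FALSE]

  a <- pmin(int$drug_id, int$partner_id)
  b <- pmax(int$drug_id, int$partner_id)
  if (length(a) > 0L) {
    key <- paste(a, b, sep = "\r")
    first <- !duplicated(key)
    desc <- vapply(split(int$description, key),
                   function(d) paste(d[nzchar(d)], collapse = " | "), "")
    edges <- data.frame(drug_a = a[first], drug_b = b[first])
    edges$description <- unname(desc[key[first]])
    edges <- edges[order(edges$drug_a, edges$drug_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(drug_a = character(), drug_b = character(),
                        description = character())
  }

  nodes <- if (keep_isolated) dataset$drugs$drug_id else
    sort(unique(c(edges$drug_a, edges$drug_b)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  net <- structure(list(graph = g, edges = edges), class = "ddi_network")
  stopifnot(sum(ddi_degree(net)) == 2L * nrow(edges))  # handshake lemma
  net
}

# Wrap an edge data frame (already unordered-unique) as a ddi_network.
network_from_edges <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$drug_a, edges$drug_b)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  structure(list(graph = g, edges = edges), class = "ddi_network")
}

#' @export
print.ddi_network <- function(x, ...) {
  cat("Adverse DDI network:", igraph::vcount(x$graph), "drugs,",
      nrow(x$edges), "interactions\n")
  invisible(x)
}

#' Node degrees in a DDI network
#'
#' @param network a `ddi_network`.
#' @param nodes drug ids (default: all nodes). Unknown nodes are an error.
#' @return named integer vector of degrees.
#' @export
ddi_degree <- function(network, nodes = NULL) {
  stopifnot(inherits(network, "ddi_network"))
  all_deg <- igraph::degree(network$graph)
  if (is.null(nodes)) return(all_deg)
  nodes <- as.character(nodes)
  unknown <- setdiff(nodes, names(all_deg))
  if (length(unknown) > 0L)
    stop("node(s) not in network: ", paste(unknown, collapse = ", "))
  all_deg[nodes]
}

#' Degree summary of a node set
#'
#' @param network a `ddi_network`.
#' @param nodes drug ids.
#' @return list with `mean` (unrounded) and `degrees` (named integer
#'   vector). Means are conventionally reported to 2 decimals.
#' @export
degree_summary <- function(network, nodes) {
  d <- ddi_degree(network, nodes)
  list(mean = mean(d), degrees = d)
}

#' Extract the disease-specific DDI subnetwork
#'
#' Keeps exactly the edges with at least one endpoint in the cohort, i.e.
#' interactions among cohort drugs (intra) and between cohort and non-cohort
#' drugs (inter); edges between two non-cohort drugs are removed. The
#' operation is idempotent.
#'
#' @param network a `ddi_network`.
#' @param cohort character vector of cohort drug ids; members missing from
#'   the network are skipped with a warning.
#' @return An object of class `scz_subnetwork`: list with `network` (the
#'   subnetwork, a `ddi_network`), `cohort` (cohort members present), and
#'   `partition` (list `n_scz_drugs`, `intra_edges`, `inter_edges`,
#'   `partner_ids`).
#' @export
extract_scz_subnetwork <- function(network, cohort) {
  stopifnot(inherits(network, "ddi_network"))
  cohort <- unique(as.character(cohort))
  missing <- setdiff(cohort, igraph::V(network$graph)$name)
  if (length(missing) > 0L)
    warning("cohort member(s) not in network, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  cohort <- setdiff(cohort, missing)

  e <- network$edges
  a_in <- e$drug_a %in% cohort
  b_in <- e$drug_b %in% cohort
  keep <- a_in | b_in
  e <- e[keep, , drop = FALSE]
  rownames(e) <- NULL
  intra <- e$drug_a %in% cohort & e$drug_b %in% cohort
  partners <- sort(setdiff(unique(c(e$drug_a, e$drug_b)), cohort))

  sub <- network_from_edges(e, nodes = sort(unique(c(cohort, partners))))
  structure(
    list(network = sub, cohort = cohort,
         partition = list(n_scz_drugs = length(cohort),
                          intra_edges = sum(intra),
                          inter_edges = sum(!intra),
                          partner_ids = partners)),
    class = "scz_subnetwork"
  )
}

#' @export
print.scz_subnetwork <- function(x, ...) {
  p <- x$partition
  cat("Disease-specific DDI subnetwork\n")
  cat("  cohort drugs:     ", p$n_scz_drugs, "\n")
  cat("  partner drugs:    ", length(p$partner_ids), "\n")
  cat("  intra-cohort edges:", p$intra_edges, "\n")
  cat("  cohort-partner edges:", p$inter_edges, "\n")
  cat("  cohort mean degree:",
      format(round(partition_mean_degree(p), 2), nsmall = 2), "\n")
  invisible(x)
}

#' Mean cohort degree from partition counts
#'
#' Intra-cohort edges are incident to two cohort drugs and so contribute
#' twice: the mean cohort degree is `(inter + 2 * intra) / n`.
#'
#' @param partition a partition list as returned inside
#'   [extract_scz_subnetwork()], or an `scz_subnetwork`.
#' @return mean degree of the cohort (unrounded).
#' @export
partition_mean_degree <- function(partition) {
  if (inherits(partition, "scz_subnetwork")) partition <- partition$partition
  if (partition$n_scz_drugs <= 0L) stop("empty cohort")
  (partition$inter_edges + 2 * partition$intra_edges) / partition$n_scz_drugs
}
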