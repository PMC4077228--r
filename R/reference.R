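#' Construct a reference interaction network
#'
#' A reference network is an experimentally derived interaction map (such as
#' a proteomics-based autophagy interaction network) onto which a mediator
#' list is overlaid. It wraps an `interactome` plus an optional assignment of
#' nodes to functional sub-networks (bait clusters).
#'
#' @param x An `interactome`, igraph, or two-column edge matrix/data frame.
#' @param baits Optional data frame with columns `accession` and
#'   `sub_network` assigning nodes to functional sub-network labels (a node
#'   may appear in several rows).
#' @return Object of class `reference_network`.
#' @export
reference_network <- function(x, baits = NULL) {
  graph <- if (inherits(x, "interactome")) x else interactome(x)
  ba <- NULL
  if (!is.null(baits)) {
    stopifnot(is.data.frame(baits),
              all(c("accession", "sub_network") %in% names(baits)))
    ba <- split(as.character(baits$sub_network), as.character(baits$accession))
    ba <- lapply(ba, function(s) sort(unique(s)))
  }
  structure(list(graph = graph, bait_assignment = ba),
            class = "reference_network")
}

#' @export
print.reference_network <- function(x, ...) {
  sz <- network_size(x$graph)
  cat(sprintf("Reference network: %d nodes, %d edges%s\n", sz[["nodes"]],
              sz[["edges"]],
              if (is.null(x$bait_assignment)) "" else
                sprintf(", %d nodes with sub-network labels",
                        length(x$bait_assignment))))
  invisible(x)
}

#' Read a bait / sub-network assignment table
#' @param path Two-column TSV (accession, sub-network label), optional header.
#' @return Data frame with columns `accession`, `sub_network`.
#' @export
read_baits <- function(path) {
  if (!file.exists(path)) abort_io("bait table not found: ", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("accession", "sub_network"),
                   colClasses = "character")
  if (nrow(df) && tolower(df$accession[1]) %in% c("accession", "protein"))
    df <- df[-1, , drop = FALSE]
  df <- df[nzchar(df$accession) & nzchar(df$sub_network), , drop = FALSE]
  if (!nrow(df)) abort_io("no bait rows in ", path)
  unique(df)
}

#' Articulation points (cut vertices)
#'
#' A node is an articulation point if removing it (with its incident edges)
#' strictly increases the number of connected components among the remaining
#' nodes — the nodes whose loss fragments the network. Computed by the
#' linear-time depth-first-search low-link algorithm.
#'
#' @param network An `interactome`, `reference_network`, or igraph.
#' @return Sorted character vector of accessions.
#' @export
articulation_points <- function(network) {
  g <- as_igraph(network)
  sort(igraph::V(g)$name[as.integer(igraph::articulation_points(g))])
}

#' Overlay mediators onto a reference network
#'
#' For each mediator: membership in the reference network, its degree there,
#' whether it is among the top-k nodes of the whole reference network by
#' degree, whether it is an articulation point of the reference network (not
#' of any overlap-induced subgraph), and its functional sub-network labels.
#' Ties at the top-k degree boundary are all included and the effective k is
#' reported (attribute `effective_k`), so no tied node is arbitrarily
#' excluded.
#'
#' @param mediators A `mediator_set` or character vector of accessions.
#' @param reference A [reference_network()].
#' @param top_k Size of the high-degree set (default 10).
#' @return Data frame of class `overlap_report`, one row per mediator:
#'   `accession`, `in_reference`, `reference_degree` (`NA` when absent),
#'   `is_articulation`, `in_top_k`, `sub_networks` (comma-joined labels).
#'   Attributes: `effective_k`, `degree_cutoff`.
#' @export
overlap_report <- function(mediators, reference, top_k = 10) {
  stopifnot(inherits(reference, "reference_network"), top_k >= 1)
  meds <- if (inherits(mediators, "mediator_set")) mediators$members
          else unique(as.character(mediators))
  g <- as_igraph(reference)
  if (!igraph::vcount(g)) stop("reference network is empty")
  deg <- igraph::degree(g)
  ds <- sort(deg, decreasing = TRUE)
  cutoff <- ds[min(top_k, length(ds))]
  top_nodes <- names(deg)[deg >= cutoff]
  arts <- articulation_points(reference)
  inref <- meds %in% names(deg)
  if (!any(inref)) warning("no mediator is present in the reference network")
  subs <- vapply(meds, function(m) {
    s <- reference$bait_assignment[[m]]
    if (is.null(s)) "" else paste(s, collapse = ",")
  }, "")
  out <- data.frame(
    accession = meds,
    in_reference = inref,
    reference_degree = ifelse(inref, as.integer(deg[meds]), NA_integer_),
    is_articulation = inref & meds %in% arts,
    in_top_k = inref & meds %in% top_nodes,
    sub_networks = unname(subs),
    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$reference_degree), -1, out$reference_degree),
                   out$accession), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "effective_k") <- length(top_nodes)
  attr(out, "degree_cutoff") <- unname(cutoff)
  class(out) <- c("overlap_report", class(out))
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap report: %d/%d mediators in reference; %d in top-k (effective k = %d), %d articulation points\n",
              sum(x$in_reference), nrow(x), sum(x$in_top_k),
              attr(x, "effective_k"), sum(x$is_articulation)))
  NextMethod()
}
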