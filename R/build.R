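#' Filter interaction records
#'
#' Cleans a raw interaction table before network construction: optionally
#' drops computationally predicted (homology-transferred) interactions,
#' removes self-interactions, and collapses duplicate pairs (A-B and B-A are
#' the same undirected interaction). The number of records removed by each
#' rule is attached as the `"removed"` attribute.
#'
#' @param records An `interaction_records` data frame from
#'   [read_interactions()].
#' @param exclude_predicted Drop records with `evidence == "predicted"`?
#'   Defaults to `TRUE` to keep only experimentally supported interactions.
#' @return Filtered `interaction_records`, with attribute `removed` (named
#'   counts: `predicted`, `self_loop`, `duplicate`).
#' @export
filter_interactions <- function(records, exclude_predicted = TRUE) {
  stopifnot(is.data.frame(records))
  n0 <- nrow(records)
  n_pred <- 0L
  if (exclude_predicted) {
    pred <- records$evidence == "predicted"
    n_pred <- sum(pred)
    records <- records[!pred, , drop = FALSE]
  }
  self <- records$protein_a == records$protein_b
  n_self <- sum(self)
  records <- records[!self, , drop = FALSE]
  dup <- duplicated(edge_key(records$protein_a, records$protein_b))
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "removed") <- c(predicted = n_pred, self_loop = n_self,
                                duplicate = n_dup)
  if (!nrow(records))
    warning("all interaction records were removed by filtering")
  class(records) <- unique(c("interaction_records", class(records)))
  records
}

# deduplicated simple graph over ALL filtered records (the full record graph)
records_graph <- function(records, disease = NULL, targets = NULL) {
  roles <- seed_roles(disease, targets)
  interactome(cbind(records$protein_a, records$protein_b),
              nodes = names(roles), roles = roles)
}

seed_roles <- function(disease = NULL, targets = NULL) {
  dg <- if (is.null(disease)) character() else seed_members(disease)
  dt <- if (is.null(targets)) character() else seed_members(targets)
  role <- c(setNames(rep("disease_seed", length(dg)), dg),
            setNames(rep("drug_target_seed", length(dt)), dt))
  both <- intersect(dg, dt)
  role[both] <- "both_seed"
  role[!duplicated(names(role))]
}

#' Build the integrated seed network
#'
#' Constructs the undirected, unweighted interaction network anchored on the
#' disease and drug-target seed sets: the node set is the seeds plus every
#' direct (one-step) interaction partner of any seed, and the edge set is the
#' full induced subgraph of the filtered record graph on those nodes (so
#' interactions among neighbours are retained, not only seed-neighbour
#' spokes). Seeds with no recorded interaction are kept as isolated nodes
#' with a warning — they legitimately contribute additional connected
#' components.
#'
#' @param records Filtered `interaction_records` (see
#'   [filter_interactions()]).
#' @param disease Disease [seed_set()].
#' @param targets Drug-target [seed_set()].
#' @return An `interactome` with node roles `disease_seed`,
#'   `drug_target_seed`, `both_seed` (present in both seed lists) or
#'   `neighbor`.
#' @export
build_integrated_network <- function(records, disease, targets) {
  dg <- seed_members(disease); dt <- seed_members(targets)
  if (!length(dg) && !length(dt)) stop("both seed sets are empty")
  seeds <- union(dg, dt)
  full <- records_graph(records)
  g <- full$graph
  present <- intersect(seeds, igraph::V(g)$name)
  nbrs <- character()
  if (length(present)) {
    nb <- igraph::adjacent_vertices(g, present)
    nbrs <- unique(igraph::V(g)$name[unlist(lapply(nb, as.integer))])
  }
  keep <- union(seeds, nbrs)
  isolated <- setdiff(seeds, present)
  if (length(isolated))
    warning(sprintf("%d seed(s) have no recorded interaction and are retained as isolated nodes",
                    length(isolated)))
  sub <- igraph::induced_subgraph(g, intersect(igraph::V(g)$name, keep))
  interactome(igraph::as_edgelist(sub),
              nodes = keep,
              roles = seed_roles(dg, dt))
}
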