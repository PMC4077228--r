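#' Degree table of a network
#'
#' The degree index of a node is the size of its neighbourhood — the number
#' of direct interaction partners — the centrality measure used to rank
#' proteins in the integrated network.
#'
#' @param network An `interactome`.
#' @return Data frame (`accession`, `degree`) sorted by decreasing degree,
#'   ties broken lexicographically by accession.
#' @export
degree_index <- function(network) {
  g <- as_igraph(network)
  d <- igraph::degree(g)
  out <- data.frame(accession = names(d), degree = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Connected components
#'
#' @param network An `interactome`.
#' @return List of character vectors (node sets), largest component first;
#'   ties by smallest member name.
#' @export
connected_components <- function(network) {
  g <- as_igraph(network)
  comp <- igraph::components(g)
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(parts, sort)
  ord <- order(-lengths(parts), vapply(parts, `[`, "", 1))
  unname(parts[ord])
}

#' Giant-component summary
#'
#' Size of the largest connected component and the fraction of the whole
#' network it covers, the standard check that a seed-anchored interactome is
#' well connected enough for path-based analysis.
#'
#' @param network A non-empty `interactome`.
#' @return Named list: `giant_nodes`, `giant_edges`, `node_pct`, `edge_pct`
#'   (percentages of totals, rounded to 2 decimals; `edge_pct` is `NA` for an
#'   edgeless network).
#' @export
giant_component_summary <- function(network) {
  g <- as_igraph(network)
  if (!igraph::vcount(g)) stop("empty network")
  comps <- connected_components(network)
  giant <- comps[[1]]
  sub <- igraph::induced_subgraph(g, giant)
  ne <- igraph::ecount(g)
  list(giant_nodes = length(giant),
       giant_edges = igraph::ecount(sub),
       node_pct = coverage_pct(length(giant), igraph::vcount(g)),
       edge_pct = if (ne) coverage_pct(igraph::ecount(sub), ne) else NA_real_)
}

#' Shortest-path statistics
#'
#' Distances are unweighted shortest-path lengths. On a disconnected network
#' the diameter is the maximum over the diameters of its components, and the
#' average path length is taken over connected (finite-distance) node pairs
#' only. Two radius conventions are reported: `radius_paper` is the smallest
#' distance between two distinct nodes — which is 1 on any network with at
#' least one edge — while `radius_standard` is the usual minimum eccentricity,
#' evaluated within the giant component.
#'
#' @param network An `interactome` with at least one edge for finite results.
#' @return Named list `diameter`, `radius_paper`, `radius_standard`,
#'   `avg_shortest_path`; all `NA` (with a warning) on an edgeless network.
#' @export
path_statistics <- function(network) {
  g <- as_igraph(network)
  if (!igraph::ecount(g)) {
    warning("network has no edges; path statistics are undefined")
    return(list(diameter = NA_real_, radius_paper = NA_real_,
                radius_standard = NA_real_, avg_shortest_path = NA_real_))
  }
  D <- igraph::distances(g)
  up <- D[upper.tri(D)]
  finite <- up[is.finite(up)]
  giant <- connected_components(network)[[1]]
  Dg <- D[giant, giant, drop = FALSE]
  ecc <- apply(Dg, 1, max)
  list(diameter = max(finite),
       radius_paper = min(finite),
       radius_standard = if (length(giant) > 1) min(ecc) else 0,
       avg_shortest_path = mean(finite))
}

#' Local clustering coefficient
#'
#' For a node of degree k with e edges among its neighbours, the clustering
#' coefficient is 2e / (k (k - 1)). Nodes of degree 0 or 1 have no neighbour
#' pair and are assigned coefficient 0; the network average is taken over all
#' nodes including them (the NetworkAnalyzer convention).
#'
#' @param network An `interactome`.
#' @param node Optional accession; if given, return that node's coefficient.
#' @return Named numeric vector of per-node coefficients, or a single value
#'   when `node` is supplied.
#' @export
clustering_coefficient <- function(network, node = NULL) {
  g <- as_igraph(network)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[igraph::degree(g) < 2] <- 0
  names(cc) <- igraph::V(g)$name
  if (!is.null(node)) {
    if (!node %in% names(cc)) stop("unknown node: ", node)
    return(cc[[node]])
  }
  cc
}

#' Average clustering coefficient
#' @param network An `interactome`.
#' @return Mean of [clustering_coefficient()] over all nodes.
#' @export
average_clustering <- function(network) {
  cc <- clustering_coefficient(network)
  if (!length(cc)) return(NA_real_)
  mean(cc)
}

#' Network topology summary
#'
#' Bundles the standard whole-network measures into one record: number of
#' connected components, diameter, both radius conventions, characteristic
#' (average shortest) path length, average number of neighbours, density,
#' degree centralization, degree heterogeneity, and average clustering
#' coefficient.
#'
#' Density is mean degree divided by (N - 1). Centralization is the Freeman
#' degree centralization, `(N / (N - 2)) * (k_max / (N - 1) - density)`: 1
#' on a star, 0 on any regular graph. Heterogeneity is the coefficient of
#' variation of the degree distribution (population standard deviation over
#' mean degree), large when connectivity concentrates in hubs.
#'
#' @param network A non-empty `interactome`.
#' @return Object of class `network_stats` (a named list; see fields above,
#'   plus `n_nodes`, `n_edges` and the giant-component summary).
#' @export
summarize_network <- function(network) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (!n) stop("empty network")
  d <- igraph::degree(g)
  ps <- path_statistics(network)
  dens <- if (n > 1) mean(d) / (n - 1) else NA_real_
  centr <- if (n >= 3) (n / (n - 2)) * (max(d) / (n - 1) - dens) else {
    warning("centralization undefined for networks with fewer than 3 nodes")
    NA_real_
  }
  het <- if (mean(d) > 0) sqrt(mean((d - mean(d))^2)) / mean(d) else NA_real_
  structure(list(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    n_components = length(connected_components(network)),
    diameter = ps$diameter,
    radius_paper = ps$radius_paper,
    radius_standard = ps$radius_standard,
    avg_shortest_path = ps$avg_shortest_path,
    avg_neighbors = mean(d),
    density = dens,
    centralization = centr,
    heterogeneity = het,
    avg_clustering = average_clustering(network),
    giant = giant_component_summary(network)
  ), class = "network_stats")
}

#' @export
print.network_stats <- function(x, digits = 3, ...) {
  cat("Network topology summary\n")
  fmt <- function(v) if (is.na(v)) "NA" else format(round(v, digits), nsmall = 0)
  rows <- c(
    "Nodes" = x$n_nodes, "Edges" = x$n_edges,
    "Number of connected components" = x$n_components,
    "Network diameter" = x$diameter,
    "Network radius (min pair distance)" = x$radius_paper,
    "Network radius (min eccentricity)" = x$radius_standard,
    "Average shortest path length" = x$avg_shortest_path,
    "Average number of neighbors" = x$avg_neighbors,
    "Network density" = x$density,
    "Network centralization" = x$centralization,
    "Network heterogeneity" = x$heterogeneity,
    "Clustering coefficient" = x$avg_clustering)
  for (nm in names(rows)) cat(sprintf("  %-36s %s\n", nm, fmt(rows[[nm]])))
  cat(sprintf("  Giant component: %d nodes (%.2f%%), %d edges (%.2f%%)\n",
              x$giant$giant_nodes, x$giant$node_pct,
              x$giant$giant_edges, x$giant$edge_pct))
  invisible(x)
}

#' @export
summary.interactome <- function(object, ...) summarize_network(object)

#' Serialize a topology summary to JSON-ready list
#' @param x A `network_stats` object.
#' @return Plain named list suitable for `jsonlite::write_json()`.
#' @export
as.list.network_stats <- function(x, ...) {
  out <- unclass(x)
  out$giant <- unclass(out$giant)
  out
}
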