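#' Construct an interactome
#'
#' An `interactome` is a simple (no self-loops, no duplicate edges),
#' undirected, unweighted graph over protein accessions, with a role label per
#' node: `"disease_seed"`, `"drug_target_seed"`, `"both_seed"` or
#' `"neighbor"`. It is the common container consumed by the topology,
#' mediator and overlap analyses.
#'
#' @param edges Two-column character matrix or data frame of undirected edges
#'   (accession pairs). Self-loops and duplicate/reversed pairs are collapsed.
#' @param nodes Optional character vector of node accessions; nodes appearing
#'   only here (not in `edges`) are kept as isolates.
#' @param roles Optional named character vector mapping accessions to roles;
#'   unnamed nodes default to `"neighbor"`.
#' @return An object of class `interactome`.
#' @examples
#' net <- interactome(rbind(c("a", "b"), c("b", "c")))
#' net
#' @export
interactome <- function(edges = NULL, nodes = NULL, roles = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2) stop("`edges` must have two columns")
    edges <- matrix(as.character(edges[, 1:2]), ncol = 2)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]  # drop self-loops
    if (nrow(edges)) {
      edges <- edges[!duplicated(edge_key(edges[, 1], edges[, 2])), , drop = FALSE]
    }
  } else {
    edges <- matrix(character(), ncol = 2)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  extra <- setdiff(as.character(nodes), igraph::V(g)$name)
  if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  role <- setNames(rep("neighbor", igraph::vcount(g)), igraph::V(g)$name)
  if (!is.null(roles)) {
    roles <- roles[names(roles) %in% names(role)]
    role[names(roles)] <- unname(roles)
  }
  new_interactome(g, role)
}

new_interactome <- function(graph, role) {
  stopifnot(igraph::is_igraph(graph))
  obj <- structure(list(graph = graph, role = role), class = "interactome")
  validate_interactome(obj)
}

#' Validate interactome invariants
#'
#' Checks that the graph is undirected and simple, every node has a role, and
#' role values are from the allowed set. Called by all constructors; exported
#' so generated fixtures can be re-checked.
#'
#' @param x An `interactome`.
#' @return `x`, invisibly usable, after passing all checks (errors otherwise).
#' @export
validate_interactome <- function(x) {
  g <- x$graph
  if (igraph::is_directed(g)) stop("interactome must be undirected")
  if (any(igraph::which_loop(g))) stop("interactome must not contain self-loops")
  if (any(igraph::which_multiple(g))) stop("interactome must not contain duplicate edges")
  if (!identical(sort(names(x$role)), sort(igraph::V(g)$name)))
    stop("role map must cover exactly the node set")
  ok <- x$role %in% c("disease_seed", "drug_target_seed", "both_seed", "neighbor")
  if (!all(ok)) stop("unknown role label: ", paste(unique(x$role[!ok]), collapse = ", "))
  x
}

as_igraph <- function(x) {
  if (inherits(x, "interactome")) x$graph
  else if (inherits(x, "reference_network")) x$graph$graph
  else if (igraph::is_igraph(x)) x
  else stop("expected an interactome or igraph object")
}

#' @export
print.interactome <- function(x, ...) {
  g <- x$graph
  cat(sprintf("Interactome: %d nodes, %d edges\n",
              igraph::vcount(g), igraph::ecount(g)))
  tab <- table(factor(x$role, levels = c("disease_seed", "drug_target_seed",
                                         "both_seed", "neighbor")))
  cat(sprintf("  roles: %d disease seeds, %d drug-target seeds, %d both, %d neighbors\n",
              tab[["disease_seed"]], tab[["drug_target_seed"]],
              tab[["both_seed"]], tab[["neighbor"]]))
  invisible(x)
}

#' Node and edge counts of an interactome
#'
#' @param x An `interactome`.
#' @return Named numeric vector with elements `nodes` and `edges`.
#' @export
network_size <- function(x) {
  g <- as_igraph(x)
  c(nodes = igraph::vcount(g), edges = igraph::ecount(g))
}

#' Nodes of an interactome
#' @param x An `interactome` (or igraph).
#' @return Character vector of accessions.
#' @export
network_nodes <- function(x) igraph::V(as_igraph(x))$name

#' Edge list of an interactome
#' @param x An `interactome` (or igraph).
#' @return Two-column character matrix, one row per undirected edge, each row
#'   in canonical (lexicographic) order, rows sorted.
#' @export
network_edges <- function(x) {
  el <- igraph::as_edgelist(as_igraph(x))
  if (!nrow(el)) return(matrix(character(), ncol = 2,
                               dimnames = list(NULL, c("protein_a", "protein_b"))))
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  dimnames(el) <- list(NULL, c("protein_a", "protein_b"))
  el
}

#' @export
plot.interactome <- function(x, ...) {
  g <- x$graph
  pal <- c(disease_seed = "#D55E00", drug_target_seed = "#0072B2",
           both_seed = "#CC79A7", neighbor = "grey70")
  cols <- pal[x$role[igraph::V(g)$name]]
  shp <- ifelse(x$role[igraph::V(g)$name] %in% c("neighbor"), "circle", "square")
  igraph::plot.igraph(g, vertex.color = cols, vertex.shape = shp,
                      vertex.size = 5, vertex.label = NA, ...)
  invisible(x)
}

#' Create a seed set
#'
#' A labelled set of protein accessions anchoring network construction:
#' either disease-associated proteins or primary drug targets. Symbols that
#' failed identifier mapping are carried along for reporting.
#'
#' @param members Character vector of accessions (deduplicated).
#' @param label `"disease"` or `"drug_target"`.
#' @param unmapped_symbols Character vector of gene symbols with no mapping.
#' @return Object of class `seed_set`.
#' @export
seed_set <- function(members, label = c("disease", "drug_target"),
                     unmapped_symbols = character()) {
  label <- match.arg(label)
  members <- unique(as.character(members))
  if (!length(members)) stop("seed set has no members")
  if (any(!nzchar(members))) stop("seed accessions must be non-empty strings")
  structure(list(label = label, members = members,
                 unmapped_symbols = unique(as.character(unmapped_symbols))),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("Seed set [%s]: %d members", x$label, length(x$members)))
  if (length(x$unmapped_symbols))
    cat(sprintf(" (%d symbols unmapped)", length(x$unmapped_symbols)))
  cat("\n")
  invisible(x)
}

seed_members <- function(x) {
  if (inherits(x, "seed_set")) x$members else unique(as.character(x))
}
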