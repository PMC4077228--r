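#' Neighbourhood union of a seed class
#'
#' The union of the direct (one-step) neighbourhoods of every seed vertex:
#' the set I of proteins with at least one interaction to the seed class. A
#' seed itself belongs to the result only when it neighbours another seed of
#' the same class — there is no self-membership by fiat. Seeds absent from
#' the network are skipped with a warning.
#'
#' @param network An `interactome`.
#' @param seeds A [seed_set()] or character vector of accessions.
#' @return Sorted character vector of accessions.
#' @export
neighbor_union <- function(network, seeds) {
  g <- as_igraph(network)
  members <- seed_members(seeds)
  present <- intersect(members, igraph::V(g)$name)
  missing <- setdiff(members, present)
  if (length(missing))
    warning(sprintf("%d seed(s) not present in the network were skipped",
                    length(missing)))
  if (!length(present)) return(character())
  nb <- igraph::adjacent_vertices(g, present)
  sort(unique(igraph::V(g)$name[unlist(lapply(nb, as.integer))]))
}

#' Mediator proteins between two seed classes
#'
#' A mediator is a protein with at least one direct interaction to a disease
#' seed AND at least one direct interaction to a drug-target seed: the
#' intersection M of the two class neighbourhoods I_DG and I_DT. Seed
#' proteins are eligible mediators (a disease protein interacting with a drug
#' target's partner mediates like any other node). Per-mediator linkage to
#' every contacted seed is recorded.
#'
#' @param network An `interactome`; use the full filtered record graph (the
#'   integrated seeds-plus-neighbours network gives the identical result,
#'   since it is the induced subgraph on the seeds and their neighbours).
#' @param disease Disease [seed_set()] (or accession vector).
#' @param targets Drug-target [seed_set()] (or accession vector).
#' @return Object of class `mediator_set`: list with `members`, `i_dg`,
#'   `i_dt`, and `linkage` (data frame `seed`, `seed_class`, `mediator`).
#' @export
mediator_set <- function(network, disease, targets) {
  dg <- seed_members(disease); dt <- seed_members(targets)
  if (!length(dg) || !length(dt)) stop("both seed sets must be non-empty")
  i_dg <- neighbor_union(network, dg)
  i_dt <- neighbor_union(network, dt)
  members <- intersect(i_dg, i_dt)
  g <- as_igraph(network)
  link_rows <- function(seeds, cls) {
    present <- intersect(seeds, igraph::V(g)$name)
    if (!length(present) || !length(members)) return(NULL)
    nb <- igraph::adjacent_vertices(g, present)
    do.call(rbind, lapply(seq_along(present), function(i) {
      m <- intersect(igraph::V(g)$name[as.integer(nb[[i]])], members)
      if (!length(m)) return(NULL)
      data.frame(seed = present[i], seed_class = cls, mediator = sort(m),
                 stringsAsFactors = FALSE)
    }))
  }
  linkage <- suppressWarnings(rbind(link_rows(dg, "disease"),
                                    link_rows(dt, "drug_target")))
  if (is.null(linkage))
    linkage <- data.frame(seed = character(), seed_class = character(),
                          mediator = character(), stringsAsFactors = FALSE)
  linkage <- linkage[order(linkage$seed_class, linkage$seed, linkage$mediator), ,
                     drop = FALSE]
  rownames(linkage) <- NULL
  structure(list(members = sort(members), i_dg = i_dg, i_dt = i_dt,
                 linkage = linkage),
            class = "mediator_set")
}

#' @export
print.mediator_set <- function(x, ...) {
  cat(sprintf("Mediator set: %d mediators (|I_DG| = %d, |I_DT| = %d, %d linkage rows)\n",
              length(x$members), length(x$i_dg), length(x$i_dt),
              nrow(x$linkage)))
  if (length(x$members))
    cat("  ", paste(head(x$members, 10), collapse = ", "),
        if (length(x$members) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Seed-mediator linkage table
#'
#' Flat table of (seed protein, seed class, mediator) associations, the
#' format used to report which disease proteins each mediator contacts.
#' Optional restrictions filter the recorded linkage without recomputation:
#' `seeds` keeps rows for a subset of seed proteins (e.g. the seeds of one
#' disease subgroup), `mediators` keeps rows for a mediator subset (e.g. the
#' mediators annotated to one process).
#'
#' @param mediators A `mediator_set`.
#' @param seeds Optional character vector of seed accessions to keep.
#' @param mediators_subset Optional character vector of mediator accessions
#'   to keep.
#' @return Data frame (`seed`, `seed_class`, `mediator`), sorted by class,
#'   seed, then mediator. Empty (with a warning) if a restriction is disjoint
#'   from the recorded linkage.
#' @export
linkage_table <- function(mediators, seeds = NULL, mediators_subset = NULL) {
  stopifnot(inherits(mediators, "mediator_set"))
  tab <- mediators$linkage
  if (!is.null(seeds)) tab <- tab[tab$seed %in% seeds, , drop = FALSE]
  if (!is.null(mediators_subset))
    tab <- tab[tab$mediator %in% mediators_subset, , drop = FALSE]
  if (!nrow(tab) && nrow(mediators$linkage))
    warning("restriction removed every linkage row")
  rownames(tab) <- NULL
  tab
}
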