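#' Simulate a synthetic interactome
#'
#' Seeded generator of simple undirected protein-interaction-like graphs.
#' Two growth models are available. `"preferential_attachment"` attaches each
#' arriving node to `m` existing nodes with probability proportional to their
#' degree, producing the heavy-tailed degree distribution characteristic of
#' interactomes. `"duplication_divergence"` mimics gene duplication: each
#' arriving node picks a random anchor, inherits each anchor edge
#' independently with probability `p_keep`, and links to the anchor itself
#' with probability `p_anchor`; a node left edgeless is connected to its
#' anchor so the graph stays free of spurious isolates.
#'
#' @param n_nodes Number of nodes (at least 5).
#' @param model `"preferential_attachment"` or `"duplication_divergence"`.
#' @param params Model parameters: `m` (edges per arrival, default 2) for
#'   preferential attachment; `p_keep` (default 0.4) and `p_anchor` (default
#'   0.7) for duplication-divergence.
#' @param rng_seed Integer seed; identical seeds give identical graphs.
#' @return An `interactome` with node names `P00001`, `P00002`, ... and all
#'   roles `"neighbor"`.
#' @export
simulate_interactome <- function(n_nodes,
                                 model = c("preferential_attachment",
                                           "duplication_divergence"),
                                 params = list(), rng_seed = 1L) {
  model <- match.arg(model)
  if (n_nodes < 5) stop("n_nodes must be at least 5")
  set.seed(rng_seed)
  nodes <- sprintf("P%05d", seq_len(n_nodes))
  if (model == "preferential_attachment") {
    m <- params$m %||% 2L
    if (m < 1) stop("preferential attachment needs m >= 1")
    g <- igraph::sample_pa(n_nodes, m = m, directed = FALSE)
    igraph::V(g)$name <- nodes
    el <- igraph::as_edgelist(g)
  } else {
    p_keep <- params$p_keep %||% 0.4
    p_anchor <- params$p_anchor %||% 0.7
    if (p_keep < 0 || p_keep > 1 || p_anchor < 0 || p_anchor > 1)
      stop("duplication-divergence needs probabilities in [0, 1]")
    adj <- list(); adj[[1]] <- 2L; adj[[2]] <- 1L  # seed dimer
    for (v in 3:n_nodes) {
      anchor <- sample.int(v - 1L, 1L)
      inherited <- adj[[anchor]][stats::runif(length(adj[[anchor]])) < p_keep]
      nb <- unique(inherited)
      if (stats::runif(1) < p_anchor) nb <- union(nb, anchor)
      if (!length(nb)) nb <- anchor
      adj[[v]] <- nb
      for (u in nb) adj[[u]] <- c(adj[[u]], v)
    }
    el <- do.call(rbind, lapply(seq_len(n_nodes), function(v) {
      to <- adj[[v]][adj[[v]] > v]
      if (length(to)) cbind(nodes[v], nodes[to]) else NULL
    }))
  }
  interactome(el, nodes = nodes)
}

#' Plant seed sets and mediator bridges
#'
#' Samples disjoint disease and drug-target seed sets from a synthetic
#' interactome, then turns `n_bridges` further nodes into guaranteed
#' mediators by wiring each to at least one seed of each class (an edge is
#' added only where the adjacency does not already exist). The planted nodes
#' are recorded as ground truth; other nodes may incidentally satisfy the
#' mediator definition too and are deliberately NOT recorded, so recovery
#' tests can distinguish guaranteed recall from incidental extras.
#'
#' @param interactome An `interactome` from [simulate_interactome()].
#' @param n_disease,n_targets Seed set sizes.
#' @param n_bridges Number of planted mediator nodes.
#' @param rng_seed Integer seed.
#' @return Object of class `synthetic_truth`: `interactome` (with bridge
#'   edges added and roles set), `disease_seeds`, `target_seeds` (seed sets),
#'   `planted_mediators`, `rng_seed`.
#' @export
plant_seeds_and_mediators <- function(interactome, n_disease, n_targets,
                                      n_bridges, rng_seed = 1L) {
  stopifnot(inherits(interactome, "interactome"))
  nodes <- network_nodes(interactome)
  if (n_disease < 1 || n_targets < 1 || n_bridges < 0 ||
      n_disease + n_targets + n_bridges > length(nodes))
    stop("infeasible seed/bridge counts for a graph of ", length(nodes), " nodes")
  set.seed(rng_seed)
  pick <- sample(nodes, n_disease + n_targets + n_bridges)
  dg <- pick[seq_len(n_disease)]
  dt <- pick[n_disease + seq_len(n_targets)]
  bridges <- if (n_bridges) pick[n_disease + n_targets + seq_len(n_bridges)] else character()
  g <- interactome$graph
  new_edges <- NULL
  for (b in bridges) {
    nb <- igraph::V(g)$name[as.integer(igraph::neighbors(g, b))]
    if (!length(intersect(nb, dg)))
      new_edges <- rbind(new_edges, c(b, sample(dg, 1)))
    if (!length(intersect(nb, dt)))
      new_edges <- rbind(new_edges, c(b, sample(dt, 1)))
  }
  el <- rbind(network_edges(interactome), new_edges)
  net <- interactome(el, nodes = nodes, roles = seed_roles(dg, dt))
  structure(list(interactome = net,
                 disease_seeds = seed_set(dg, "disease"),
                 target_seeds = seed_set(dt, "drug_target"),
                 planted_mediators = sort(bridges),
                 planted_enriched_terms = character(),
                 annotations = NULL,
                 reference = NULL,
                 rng_seed = rng_seed),
            class = "synthetic_truth")
}

#' Plant annotation terms with known enrichment
#'
#' Generates a term-to-gene annotation set over the interactome's node
#' universe. Background terms draw a fixed number of genes uniformly.
#' Enriched terms annotate each gene with its base probability, multiplied by
#' `effect` (capped at 1) for the planted mediators — so the planted
#' mediator list is genuinely over-represented in those terms and their IDs
#' are recorded as ground truth. `effect = 1` plants nothing (uniform null).
#'
#' @param truth A `synthetic_truth` from [plant_seeds_and_mediators()].
#' @param n_terms Total number of terms.
#' @param enriched_terms Number of enriched terms (0 allowed; forced to 0
#'   when `effect` is 1).
#' @param effect Enrichment odds multiplier (> 1 for planted terms).
#' @param term_size_range Integer range of background term sizes.
#' @param rng_seed Integer seed.
#' @return `truth` updated with `annotations` (an [annotation_set()]) and
#'   `planted_enriched_terms`.
#' @export
plant_annotations <- function(truth, n_terms = 40, enriched_terms = 2,
                              effect = 10, term_size_range = c(10, 60),
                              rng_seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), n_terms >= 1)
  if (enriched_terms > 0 && effect <= 1) enriched_terms <- 0L
  set.seed(rng_seed)
  genes <- network_nodes(truth$interactome)
  N <- length(genes)
  planted <- truth$planted_mediators
  ids <- sprintf("T%03d", seq_len(n_terms))
  enr <- if (enriched_terms) sort(sample(ids, enriched_terms)) else character()
  t2g <- setNames(vector("list", n_terms), ids)
  size_pool <- seq(term_size_range[1], term_size_range[2])
  sizes <- size_pool[sample.int(length(size_pool), n_terms, replace = TRUE)]
  for (i in seq_len(n_terms)) {
    if (ids[i] %in% enr) {
      p0 <- sizes[i] / N
      p <- ifelse(genes %in% planted, pmin(1, effect * p0), p0)
      memb <- genes[stats::runif(N) < p]
      if (!length(memb)) memb <- sample(genes, 1)
    } else {
      memb <- sample(genes, sizes[i])
    }
    t2g[[i]] <- memb
  }
  truth$annotations <- annotation_set(t2g)
  truth$planted_enriched_terms <- enr
  truth
}

#' Simulate a reference interaction network containing known mediators
#'
#' Builds a duplication-divergence reference graph (whose leaves and bridges
#' give it a realistic articulation-point structure) and relabels some of its
#' nodes with mediator accessions from the synthetic truth: `n_top_overlap`
#' mediators are placed on the highest-degree positions (so they should be
#' recovered by top-k degree ranking) and the remaining `n_overlap -
#' n_top_overlap` on random positions. A bait table assigns sub-network
#' labels to a random subset of nodes.
#'
#' @param truth A `synthetic_truth` (mediators are taken from the full
#'   mediator set of its interactome).
#' @param n_nodes Reference network size.
#' @param n_overlap Number of mediators present in the reference network.
#' @param n_top_overlap How many of those sit on top-degree positions.
#' @param n_subnetworks Number of functional sub-network labels.
#' @param rng_seed Integer seed.
#' @return `truth` updated with `reference` (a [reference_network()]) and
#'   `planted_top_mediators` (those placed on top-degree positions).
#' @export
simulate_reference <- function(truth, n_nodes = 120, n_overlap = 20,
                               n_top_overlap = 6, n_subnetworks = 5,
                               rng_seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), n_top_overlap <= n_overlap)
  meds <- suppressWarnings(
    mediator_set(truth$interactome, truth$disease_seeds,
                 truth$target_seeds)$members)
  if (n_overlap > length(meds))
    stop("n_overlap exceeds the number of available mediators (", length(meds), ")")
  g <- simulate_interactome(n_nodes, "duplication_divergence",
                            list(p_keep = 0.3, p_anchor = 0.8),
                            rng_seed = rng_seed)$graph
  igraph::V(g)$name <- sprintf("R%04d", seq_len(n_nodes))
  deg <- igraph::degree(g)
  chosen <- sample(meds, n_overlap)
  top_meds <- chosen[seq_len(n_top_overlap)]
  other_meds <- setdiff(chosen, top_meds)
  top_pos <- names(sort(deg, decreasing = TRUE))[seq_len(n_top_overlap)]
  rest_pos <- sample(setdiff(igraph::V(g)$name, top_pos), length(other_meds))
  relabel <- c(setNames(top_meds, top_pos), setNames(other_meds, rest_pos))
  nm <- igraph::V(g)$name
  nm[match(names(relabel), nm)] <- unname(relabel)
  igraph::V(g)$name <- nm
  labelled <- sample(nm, min(n_nodes, 3 * n_subnetworks + n_overlap))
  baits <- data.frame(
    accession = labelled,
    sub_network = sprintf("subnet_%02d",
                          sample.int(n_subnetworks, length(labelled),
                                     replace = TRUE)),
    stringsAsFactors = FALSE)
  truth$reference <- reference_network(
    interactome(igraph::as_edgelist(g), nodes = nm), baits = baits)
  truth$planted_top_mediators <- sort(top_meds)
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  sz <- network_size(x$interactome)
  cat(sprintf("Synthetic truth (seed %d): %d nodes, %d edges\n", x$rng_seed,
              sz[["nodes"]], sz[["edges"]]))
  cat(sprintf("  %d disease seeds, %d drug-target seeds, %d planted mediators\n",
              length(x$disease_seeds$members), length(x$target_seeds$members),
              length(x$planted_mediators)))
  if (!is.null(x$annotations))
    cat(sprintf("  %d annotation terms (%d enriched: %s)\n",
                length(x$annotations$term_to_genes),
                length(x$planted_enriched_terms),
                paste(x$planted_enriched_terms, collapse = ", ")))
  if (!is.null(x$reference)) print(x$reference)
  invisible(x)
}

#' Paper-scale-mini synthetic study
#'
#' The default end-to-end fixture: a 500-node preferential-attachment
#' interactome (about one thousand interactions, mean degree ~4 — the same
#' order of sparsity as a seed-anchored human interactome at one-seventh
#' scale), 30 disease seeds, 40 drug-target seeds, 15 planted mediator
#' bridges, 40 annotation terms of which 2 are enriched in the planted
#' mediators at effect 10, and a 120-node reference network containing 20
#' mediators (6 on top-degree positions) across 5 sub-networks.
#'
#' @param rng_seed Integer master seed; the stage seeds are derived from it.
#' @return A complete `synthetic_truth`.
#' @export
paper_scale_mini <- function(rng_seed = 1L) {
  rng_seed <- as.integer(rng_seed)
  net <- simulate_interactome(500, "preferential_attachment", list(m = 2),
                              rng_seed = rng_seed)
  truth <- plant_seeds_and_mediators(net, n_disease = 30, n_targets = 40,
                                     n_bridges = 15, rng_seed = rng_seed + 1L)
  truth <- plant_annotations(truth, n_terms = 40, enriched_terms = 2,
                             effect = 10, rng_seed = rng_seed + 2L)
  truth <- simulate_reference(truth, n_nodes = 120, n_overlap = 20,
                              n_top_overlap = 6, n_subnetworks = 5,
                              rng_seed = rng_seed + 3L)
  truth$rng_seed <- rng_seed
  truth
}

#' Write a synthetic study to disk in the pipeline's input formats
#'
#' Materialises a `synthetic_truth` as the exact file set
#' [run_full_analysis()] consumes: an i2d-style interaction TSV (including
#' reversed duplicate rows and decoy predicted interactions, so the
#' filtering stage has real work to do), seed symbol lists, a
#' symbol-to-accession mapping, a term-gene annotation TSV, the reference
#' edge list, a bait table, and a `truth.json` ground-truth record.
#'
#' @param truth A complete `synthetic_truth`.
#' @param dir Output directory (created if needed).
#' @param n_decoy_predicted Number of decoy predicted interactions to add.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_synthetic_fixtures <- function(truth, dir, n_decoy_predicted = 40) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(truth$rng_seed + 7L)
  p <- function(f) file.path(dir, f)
  el <- network_edges(truth$interactome)
  nodes <- network_nodes(truth$interactome)
  # decoy predicted interactions on node pairs that are NOT edges
  have <- edge_key(el[, 1], el[, 2])
  decoys <- NULL
  while (is.null(decoys) || nrow(decoys) < n_decoy_predicted) {
    a <- sample(nodes, n_decoy_predicted, replace = TRUE)
    b <- sample(nodes, n_decoy_predicted, replace = TRUE)
    ok <- a != b & !edge_key(a, b) %in% have
    decoys <- unique(rbind(decoys, cbind(a[ok], b[ok])))
  }
  decoys <- decoys[seq_len(n_decoy_predicted), , drop = FALSE]
  dup_idx <- sample(nrow(el), min(5, nrow(el)))
  ppi <- rbind(
    data.frame(a = el[, 1], b = el[, 2], src = "sim", ev = "experimental"),
    data.frame(a = el[dup_idx, 2], b = el[dup_idx, 1], src = "sim",
               ev = "experimental"),  # reversed duplicates
    data.frame(a = decoys[, 1], b = decoys[, 2], src = "sim_homology",
               ev = "predicted"))
  writeLines(c("uidA\tuidB\tsource\tevidence",
               sprintf("%s\t%s\t%s\t%s", ppi$a, ppi$b, ppi$src, ppi$ev)),
             p("ppi.tsv"))
  sym <- function(acc) paste0("g_", acc)
  writeLines(sym(truth$disease_seeds$members), p("disease_symbols.txt"))
  writeLines(sym(truth$target_seeds$members), p("target_symbols.txt"))
  writeLines(sprintf("%s\t%s", sym(nodes), nodes), p("mapping.tsv"))
  t2g <- truth$annotations$term_to_genes
  writeLines(unlist(lapply(names(t2g), function(t)
    sprintf("%s\t%s", t, t2g[[t]]))), p("annotations.tsv"))
  ref_el <- network_edges(truth$reference$graph)
  writeLines(c("uidA\tuidB\tsource\tevidence",
               sprintf("%s\t%s\tref\texperimental", ref_el[, 1], ref_el[, 2])),
             p("reference.tsv"))
  ba <- truth$reference$bait_assignment
  writeLines(unlist(lapply(sort(names(ba)), function(a)
    sprintf("%s\t%s", a, ba[[a]]))), p("baits.tsv"))
  jsonlite::write_json(list(
    rng_seed = truth$rng_seed,
    n_nodes = length(nodes),
    n_edges = nrow(el),
    disease_seeds = truth$disease_seeds$members,
    target_seeds = truth$target_seeds$members,
    planted_mediators = truth$planted_mediators,
    planted_enriched_terms = truth$planted_enriched_terms,
    planted_top_mediators = truth$planted_top_mediators %||% character()),
    p("truth.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(c(ppi = p("ppi.tsv"), disease = p("disease_symbols.txt"),
              targets = p("target_symbols.txt"), mapping = p("mapping.tsv"),
              annotations = p("annotations.tsv"), reference = p("reference.tsv"),
              baits = p("baits.tsv"), truth = p("truth.json")))
}
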