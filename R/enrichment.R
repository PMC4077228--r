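#' Hypergeometric upper-tail probability
#'
#' The probability of observing at least `x` annotated genes in a query of
#' size `n`, when `K` of the `N` background genes carry the annotation:
#' P(X >= x) for X ~ Hypergeometric(N, K, n). Evaluated through the
#' log-space-stable distribution function, so very small tails do not
#' underflow. Vectorised over all arguments.
#'
#' @param x Overlap count(s), 0 <= x <= n.
#' @param n Query size(s), n <= N.
#' @param K Annotation (term) size(s) in the background, K <= N.
#' @param N Background universe size(s).
#' @return p-value(s) in (0, 1]; `x = 0` gives exactly 1.
#' @examples
#' hypergeom_tail(1, 1, 3, 10)  # 0.3
#' @export
hypergeom_tail <- function(x, n, K, N) {
  if (any(x < 0) || any(x > n) || any(n > N) || any(K > N) || any(K < 0))
    stop("invalid hypergeometric configuration: need 0 <= x <= n <= N and 0 <= K <= N")
  phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Annotation-term over-representation test
#'
#' Tests each annotation term for over-representation in a query gene list
#' using the exact hypergeometric upper tail. The background universe
#' defaults to every gene annotated to at least one term in `annotations`;
#' pass e.g. the network node set to use a different universe. Query genes
#' outside the background are dropped with a warning and do not count toward
#' the query size. Significance is declared on the raw p-value at `alpha`
#' (the convention of the original analysis, threshold 0.001);
#' Benjamini-Hochberg adjusted values are reported alongside so false
#' discovery rate control can be applied instead.
#'
#' @param query Character vector of gene/protein IDs (e.g. mediators).
#' @param annotations An [annotation_set()].
#' @param background Optional character vector overriding the default
#'   universe.
#' @param alpha Raw p-value significance threshold (default 0.001).
#' @return Data frame of class `enrichment_result`, one row per term with at
#'   least one query gene: `term`, `term_name`, `x` (overlap), `n` (effective
#'   query size), `K` (term size in background), `N` (background size),
#'   `p_raw`, `p_adjusted` (BH), `significant`; sorted by `p_raw`.
#' @export
enrich_terms <- function(query, annotations, background = NULL, alpha = 0.001) {
  stopifnot(inherits(annotations, "annotation_set"))
  t2g <- annotations$term_to_genes
  if (is.null(background))
    background <- unique(unlist(t2g, use.names = FALSE))
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  eff <- intersect(query, background)
  if (length(eff) < length(query))
    warning(sprintf("%d query gene(s) outside the background were dropped",
                    length(query) - length(eff)))
  if (!length(eff)) stop("no query gene is present in the background universe")
  N <- length(background); n <- length(eff)
  rows <- lapply(names(t2g), function(term) {
    genes <- intersect(t2g[[term]], background)
    x <- length(intersect(genes, eff))
    if (!x) return(NULL)
    data.frame(term = term, x = x, n = n, K = length(genes), N = N,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(term = character(), x = integer(), n = integer(),
                      K = integer(), N = integer(), stringsAsFactors = FALSE)
  res$p_raw <- if (nrow(res)) hypergeom_tail(res$x, res$n, res$K, res$N) else numeric()
  res$p_adjusted <- p.adjust(res$p_raw, method = "BH")
  res$significant <- res$p_raw < alpha
  nm <- annotations$term_names
  res$term_name <- if (is.null(nm)) res$term else {
    lbl <- unname(nm[res$term]); ifelse(is.na(lbl), res$term, lbl)
  }
  res <- res[order(res$p_raw, res$term),
             c("term", "term_name", "x", "n", "K", "N",
               "p_raw", "p_adjusted", "significant")]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  class(res) <- c("enrichment_result", class(res))
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: %d term(s) tested, %d significant at raw p < %g\n",
              nrow(x), sum(x$significant), attr(x, "alpha") %||% NA))
  NextMethod()
}

# ancestors of a term (including itself) in an is_a parent map
term_ancestors <- function(term, parents) {
  seen <- character(); stack <- term
  while (length(stack)) {
    t <- stack[[1]]; stack <- stack[-1]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, parents[[t]])
  }
  seen
}

# propagated annotation counts: a gene annotated to t counts for every
# ancestor of t (standard information-content convention)
propagated_genes <- function(annotations) {
  parents <- annotations$ontology_parents
  t2g <- annotations$term_to_genes
  if (is.null(parents)) return(t2g)
  terms <- union(names(t2g), names(parents))
  out <- setNames(vector("list", length(terms)), terms)
  for (t in names(t2g)) {
    for (a in term_ancestors(t, parents)) out[[a]] <- union(out[[a]], t2g[[t]])
  }
  out[lengths(out) > 0]
}

#' Semantic similarity between two annotation terms
#'
#' Two measures are available. `"jaccard"` needs no ontology: the Jaccard
#' index of the two annotated gene sets. `"lin"` requires an `is_a` DAG in
#' the annotation set: with information content IC(t) = -log(K_t / N) from
#' propagated annotation counts, Lin similarity is 2 IC(MICA) / (IC(t1) +
#' IC(t2)), where MICA is the most informative common ancestor.
#'
#' @param t1,t2 Term IDs.
#' @param annotations An [annotation_set()].
#' @param method `"jaccard"` or `"lin"`.
#' @return Similarity in \[0, 1\].
#' @export
term_similarity <- function(t1, t2, annotations, method = c("jaccard", "lin")) {
  method <- match.arg(method)
  stopifnot(inherits(annotations, "annotation_set"))
  if (method == "jaccard") {
    g1 <- annotations$term_to_genes[[t1]]
    g2 <- annotations$term_to_genes[[t2]]
    if (is.null(g1) || is.null(g2)) stop("both terms must be annotated")
    u <- length(union(g1, g2))
    return(if (u) length(intersect(g1, g2)) / u else 0)
  }
  parents <- annotations$ontology_parents
  if (is.null(parents))
    stop("lin similarity requires an ontology DAG in the annotation set")
  prop <- propagated_genes(annotations)
  N <- length(unique(unlist(prop, use.names = FALSE)))
  ic <- function(t) {
    k <- length(prop[[t]])
    if (!k) stop("term has no propagated annotation: ", t)
    -log(k / N)
  }
  common <- intersect(term_ancestors(t1, parents), term_ancestors(t2, parents))
  common <- common[common %in% names(prop)]
  if (!length(common)) return(0)
  ic1 <- ic(t1); ic2 <- ic(t2)
  if (ic1 + ic2 == 0) return(0)  # both at the root: no information
  mica <- max(vapply(common, ic, 0))
  2 * mica / (ic1 + ic2)
}

#' Similarity graph over significant terms
#'
#' Builds the term graph used to visualise an enrichment result: nodes are
#' the significant terms (carrying their raw p-values), and edges are the
#' strongest pairwise term similarities. All C(T, 2) similarities are
#' computed and ranked; the top `ceiling(kept_fraction * C(T, 2))` pairs with
#' nonzero similarity become edges, with every pair tied at the cutoff value
#' also kept (so the result does not depend on input order). The default
#' keeps 3% of pairs.
#'
#' @param results An `enrichment_result` (only `significant` rows are used)
#'   or a data frame with columns `term` and `p_raw`.
#' @param annotations An [annotation_set()].
#' @param kept_fraction Fraction of strongest pairs kept as edges.
#' @param method Similarity measure, see [term_similarity()].
#' @return Object of class `term_graph`: list with `graph` (igraph, edge
#'   attribute `similarity`, vertex attributes `p_raw`, `label`) and
#'   `kept_fraction`. Fewer than two significant terms give an empty graph
#'   with a warning.
#' @export
build_term_graph <- function(results, annotations, kept_fraction = 0.03,
                             method = c("jaccard", "lin")) {
  method <- match.arg(method)
  stopifnot(kept_fraction > 0, kept_fraction <= 1)
  if ("significant" %in% names(results))
    results <- results[results$significant, , drop = FALSE]
  terms <- sort(unique(results$term))
  pmap <- setNames(results$p_raw[match(terms, results$term)], terms)
  labmap <- if ("term_name" %in% names(results))
    setNames(results$term_name[match(terms, results$term)], terms) else
      setNames(terms, terms)
  if (length(terms) < 2) {
    warning("fewer than 2 significant terms; term graph is empty")
    g <- igraph::make_empty_graph(n = length(terms), directed = FALSE)
    if (length(terms)) {
      igraph::V(g)$name <- terms
      igraph::V(g)$p_raw <- unname(pmap[terms])
      igraph::V(g)$label <- unname(labmap[terms])
    }
    return(structure(list(graph = g, kept_fraction = kept_fraction),
                     class = "term_graph"))
  }
  pairs <- t(combn(terms, 2))
  sim <- vapply(seq_len(nrow(pairs)), function(i)
    term_similarity(pairs[i, 1], pairs[i, 2], annotations, method), 0)
  n_keep <- ceiling(kept_fraction * nrow(pairs))
  ord <- order(-sim)
  cutoff <- sim[ord[min(n_keep, length(ord))]]
  keep <- sim >= cutoff & sim > 0
  g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE], directed = FALSE)
  miss <- setdiff(terms, igraph::V(g)$name)
  if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
  igraph::E(g)$similarity <- sim[keep][match(
    edge_key(igraph::as_edgelist(g)[, 1], igraph::as_edgelist(g)[, 2]),
    edge_key(pairs[keep, 1], pairs[keep, 2]))]
  igraph::V(g)$p_raw <- unname(pmap[igraph::V(g)$name])
  igraph::V(g)$label <- unname(labmap[igraph::V(g)$name])
  structure(list(graph = g, kept_fraction = kept_fraction),
            class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("Term graph: %d significant terms, %d similarity edges (top %.1f%% of pairs)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              100 * x$kept_fraction))
  invisible(x)
}

#' @export
plot.term_graph <- function(x, ...) {
  g <- x$graph
  p <- igraph::V(g)$p_raw
  shade <- if (all(is.na(p))) rep(0.5, length(p)) else {
    lp <- -log10(p); (lp - min(lp)) / max(1e-9, diff(range(lp)))
  }
  igraph::plot.igraph(g, vertex.color = grDevices::rgb(1 - shade, shade, 0.2),
                      vertex.size = 8, vertex.label.cex = 0.7,
                      edge.width = 1 + 3 * (igraph::E(g)$similarity %||% 1), ...)
  invisible(x)
}

#' Drop redundant significant terms
#'
#' A light redundancy filter over an enrichment result, standing in for full
#' dispensability-based summarisation: when a term and one of its ontology
#' descendants are both significant, the ancestor is dropped if the
#' descendant has the smaller raw p-value (the more specific term explains
#' the signal). Requires an ontology DAG; without one the result is returned
#' unchanged.
#'
#' @param results An `enrichment_result`.
#' @param annotations An [annotation_set()] with `ontology_parents`.
#' @return `results` with redundant significant rows removed.
#' @export
prune_redundant_terms <- function(results, annotations) {
  parents <- annotations$ontology_parents
  if (is.null(parents)) return(results)
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) < 2) return(results)
  p <- setNames(sig$p_raw, sig$term)
  drop <- vapply(sig$term, function(t) {
    anc <- setdiff(term_ancestors(t, parents), t)
    # t is an ancestor of s iff t is in ancestors(s); invert: drop ancestor a
    # when some significant descendant has smaller p
    any(vapply(setdiff(sig$term, t), function(s)
      t %in% term_ancestors(s, parents) && p[[s]] < p[[t]], TRUE))
  }, TRUE)
  keep_terms <- c(sig$term[!drop], results$term[!results$significant])
  out <- results[results$term %in% keep_terms, , drop = FALSE]
  rownames(out) <- NULL
  out
}
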