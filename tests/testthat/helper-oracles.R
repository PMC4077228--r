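# Independent brute-force oracles. These deliberately avoid igraph and
# phyper: adjacency matrices, flood fill, Floyd-Warshall, neighbour-pair
# enumeration, per-node deletion, and exhaustive subset enumeration.

o_rand_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  edges <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  list(nodes = nodes, edges = edges)
}

o_adjacency <- function(nodes, edges) {
  A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      A[edges[i, 1], edges[i, 2]] <- 1L
      A[edges[i, 2], edges[i, 1]] <- 1L
    }
  }
  A
}

o_degrees <- function(nodes, edges) rowSums(o_adjacency(nodes, edges))

o_components <- function(nodes, edges) {
  A <- o_adjacency(nodes, edges)
  unseen <- nodes
  comps <- list()
  while (length(unseen)) {
    frontier <- unseen[1]; comp <- character()
    while (length(frontier)) {
      comp <- union(comp, frontier)
      frontier <- setdiff(nodes[colSums(A[frontier, , drop = FALSE]) > 0], comp)
    }
    comps[[length(comps) + 1]] <- sort(comp)
    unseen <- setdiff(unseen, comp)
  }
  ord <- order(-lengths(comps), vapply(comps, `[`, "", 1))
  comps[ord]
}

o_distances <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  A <- o_adjacency(nodes, edges)
  D[A == 1L] <- 1
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

o_clustering <- function(nodes, edges) {
  A <- o_adjacency(nodes, edges)
  vapply(nodes, function(v) {
    nb <- nodes[A[v, ] == 1L]
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, 0)
}

o_articulation <- function(nodes, edges) {
  base <- length(o_components(nodes, edges))
  is_art <- vapply(nodes, function(v) {
    rest <- setdiff(nodes, v)
    if (!length(rest)) return(FALSE)
    keep <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
    # deleting an isolate gives base - 1 components, a non-cut node base;
    # only a true cut vertex pushes the count above base
    length(o_components(rest, keep)) > base
  }, TRUE)
  sort(nodes[is_art])
}

# exact tail P(X >= x) by enumerating every size-n draw from 1..N with the
# annotated genes being 1..K
o_hyper_tail_enum <- function(x, n, K, N) {
  if (n == 0) return(if (x == 0) 1 else 0)
  draws <- combn(N, n)
  ov <- colSums(draws <= K)
  mean(ov >= x)
}

# exact tail and pmf from log-binomial coefficients (no phyper/dhyper)
o_hyper_pmf <- function(x, n, K, N) {
  exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
}
o_hyper_tail_lchoose <- function(x, n, K, N) {
  xs <- x:min(n, K)
  if (!length(xs)) return(0)
  sum(o_hyper_pmf(xs, n, K, N))
}

o_interactome <- function(edges, nodes = NULL) {
  interactome(edges, nodes = nodes)
}
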