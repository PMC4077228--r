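test_that("hypergeometric tail matches enumeration and analytic cases", {
  expect_equal(hypergeom_tail(0, 5, 3, 10), 1)          # whole support
  expect_equal(hypergeom_tail(1, 1, 3, 10), 3 / 10)     # single draw = K/N
  # all five drawn from a five-gene term: 1 / C(10,5)
  expect_equal(hypergeom_tail(5, 5, 5, 10), o_hyper_tail_enum(5, 5, 5, 10))
  expect_equal(hypergeom_tail(5, 5, 5, 10), 1 / choose(10, 5))
  # spot-check a batch of configurations against subset enumeration
  for (cfg in list(c(2, 4, 5, 9), c(1, 3, 2, 8), c(3, 6, 4, 11), c(0, 2, 7, 12))) {
    expect_equal(hypergeom_tail(cfg[1], cfg[2], cfg[3], cfg[4]),
                 o_hyper_tail_enum(cfg[1], cfg[2], cfg[3], cfg[4]))
  }
  expect_error(hypergeom_tail(5, 3, 2, 10), "invalid")
  expect_error(hypergeom_tail(1, 2, 11, 10), "invalid")
})

test_that("tail probability is monotone non-increasing in the overlap", {
  for (cfg in list(c(20, 8, 50), c(10, 10, 30), c(5, 3, 12))) {
    n <- cfg[1]; K <- cfg[2]; N <- cfg[3]
    p <- hypergeom_tail(0:min(n, K), n, K, N)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p > 0 & p <= 1))
  }
})

test_that("term over-representation test counts and significance bookkeeping", {
  bg <- sprintf("g%02d", 1:20)
  ann <- annotation_set(list(A = bg[1:5], B = bg[3:12]))
  res <- enrich_terms(bg[1:5], ann, background = bg)
  a <- res[res$term == "A", ]
  expect_equal(a$x, 5); expect_equal(a$n, 5); expect_equal(a$K, 5)
  expect_equal(a$N, 20)
  expect_equal(a$p_raw, 1 / choose(20, 5))
  expect_true(a$significant)          # 6.45e-5 < 0.001
  expect_equal(res$term[1], "A")      # sorted by p_raw

  # query gene annotated nowhere still counts in n, never in x
  ann2 <- annotation_set(list(A = bg[1:5]))
  res2 <- enrich_terms(c(bg[1:2], "g99"), ann2, background = c(bg, "g99"))
  expect_equal(res2$n, 3); expect_equal(res2$x, 2)

  expect_warning(res3 <- enrich_terms(c(bg[1], "outside"), ann, background = bg),
                 "outside the background")
  expect_equal(res3$n[1], 1)
  expect_error(suppressWarnings(enrich_terms("outside", ann, background = bg)),
               "no query gene")
})

test_that("BH adjustment is reported alongside raw p-values", {
  bg <- sprintf("g%02d", 1:30)
  ann <- annotation_set(list(A = bg[1:5], B = bg[1:10], C = bg[20:25]))
  res <- enrich_terms(bg[1:6], ann, background = bg)
  expect_equal(res$p_adjusted, p.adjust(res$p_raw, "BH"))
  expect_true(all(res$p_adjusted >= res$p_raw))
})

test_that("term similarity: jaccard on gene sets, lin on the is_a DAG", {
  bg <- sprintf("g%02d", 1:10)
  ann <- annotation_set(list(A = bg[1:4], B = bg[1:4], C = bg[5:6]))
  expect_equal(term_similarity("A", "B", ann), 1)
  expect_equal(term_similarity("A", "C", ann), 0)
  expect_equal(term_similarity("B", "C", ann, method = "jaccard"), 0)
  expect_error(term_similarity("A", "B", ann, method = "lin"),
               "requires an ontology")

  # hand evaluation on the toy DAG: IC(A) = -log 0.4, IC(B) = -log 0.2,
  # MICA(A, B) = A, lin = 2 IC(A) / (IC(A) + IC(B))
  dag <- toy_dag_annotations()
  expect_equal(term_similarity("A", "B", dag, method = "lin"),
               2 * (-log(0.4)) / (-log(0.4) - log(0.2)))
  expect_equal(term_similarity("root", "root", dag, method = "lin"), 0)
})

test_that("term graph keeps the strongest fraction of pairs, ties included", {
  # nested terms of prime sizes: jaccard(i, j) = p_i / p_j, all 45 pairwise
  # similarities distinct, so the cutoff boundary is tie-free by construction
  primes <- c(11, 13, 17, 19, 23, 29, 31, 37, 41, 43)
  bg <- sprintf("g%03d", 1:43)
  t2g <- setNames(lapply(primes, function(p) bg[1:p]), sprintf("T%02d", 1:10))
  ann <- annotation_set(t2g)
  res <- data.frame(term = names(t2g), p_raw = seq(1e-6, 1e-5, length.out = 10),
                    significant = TRUE)
  tg <- build_term_graph(res, ann, kept_fraction = 0.03)
  expect_equal(igraph::ecount(tg$graph), ceiling(0.03 * choose(10, 2)))  # 2
  expect_equal(igraph::vcount(tg$graph), 10)

  # two significant terms with nonzero similarity -> one edge
  ann2 <- annotation_set(list(X = bg[1:10], Y = bg[5:14]))
  res2 <- data.frame(term = c("X", "Y"), p_raw = c(1e-5, 1e-4), significant = TRUE)
  expect_equal(igraph::ecount(build_term_graph(res2, ann2)$graph), 1)

  # all-zero similarities -> no edges
  ann3 <- annotation_set(list(X = bg[1:5], Y = bg[6:10], Z = bg[11:15]))
  res3 <- data.frame(term = c("X", "Y", "Z"), p_raw = rep(1e-5, 3),
                     significant = TRUE)
  expect_equal(igraph::ecount(build_term_graph(res3, ann3)$graph), 0)

  # fewer than two terms -> empty graph with warning
  expect_warning(tg1 <- build_term_graph(res2[1, ], ann2), "fewer than 2")
  expect_equal(igraph::ecount(tg1$graph), 0)
})

test_that("term graph edges are invariant to the input ordering of terms", {
  set.seed(91)
  bg <- sprintf("g%03d", 1:150)
  t2g <- setNames(lapply(1:8, function(i) sample(bg, 25)), sprintf("T%02d", 1:8))
  ann <- annotation_set(t2g)
  res <- data.frame(term = names(t2g), p_raw = runif(8, 1e-6, 1e-4),
                    significant = TRUE)
  g1 <- build_term_graph(res, ann, kept_fraction = 0.1)$graph
  g2 <- build_term_graph(res[sample(8), ], ann, kept_fraction = 0.1)$graph
  expect_equal(network_edges(g1), network_edges(g2))
})

test_that("redundancy filter drops ancestors explained by a stronger descendant", {
  dag <- toy_dag_annotations()
  res <- data.frame(term = c("root", "A", "B"),
                    term_name = c("root", "A", "B"),
                    x = c(5, 4, 2), n = 5, K = c(10, 4, 2), N = 10,
                    p_raw = c(1e-4, 1e-6, 1e-3), p_adjusted = NA,
                    significant = TRUE, stringsAsFactors = FALSE)
  kept <- prune_redundant_terms(res, dag)
  # A (descendant of root, smaller p) evicts root; B stays: its ancestor A
  # is dropped only in favour of descendants, and B has none significant
  expect_setequal(kept$term, c("A", "B"))
  # without a DAG the filter is a no-op
  ann <- annotation_set(list(A = "g1"))
  expect_equal(prune_redundant_terms(res, ann), res)
})
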