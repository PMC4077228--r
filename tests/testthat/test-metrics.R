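tri <- interactome(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
star3 <- interactome(rbind(c("c", "l1"), c("c", "l2"), c("c", "l3")))
star4 <- interactome(cbind("hub", paste0("l", 1:4)))
path3 <- interactome(rbind(c("a", "b"), c("b", "c")))

test_that("degree table matches hand cases and the handshake identity", {
  expect_equal(degree_index(tri)$degree, c(2, 2, 2))
  d <- degree_index(star3)
  expect_equal(d$accession[1], "c")
  expect_equal(d$degree, c(3, 1, 1, 1))
  for (seed in 1:10) {
    g <- o_rand_graph(40, 0.1, seed = 600 + seed)
    net <- interactome(g$edges, nodes = g$nodes)
    dt <- degree_index(net)
    expect_equal(sum(dt$degree), 2 * nrow(network_edges(net)))
    oracle <- o_degrees(g$nodes, g$edges)
    expect_equal(setNames(dt$degree, dt$accession)[g$nodes],
                 setNames(as.integer(oracle), g$nodes))
  }
})

test_that("connected components partition the nodes, largest first", {
  two <- interactome(rbind(c("a", "b"), c("c", "d")))
  expect_length(connected_components(two), 2)
  solo <- interactome(nodes = "x")
  expect_equal(connected_components(solo), list("x"))
  g <- o_rand_graph(50, 0.03, seed = 611)
  net <- interactome(g$edges, nodes = g$nodes)
  expect_equal(connected_components(net), o_components(g$nodes, g$edges))
})

test_that("giant-component summary reports coverage percentages", {
  gs <- giant_component_summary(tri)
  expect_equal(gs$node_pct, 100)
  expect_equal(gs$edge_pct, 100)
  mixed <- interactome(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                             c("x", "y")))
  gs2 <- giant_component_summary(mixed)
  expect_equal(gs2$giant_nodes, 3)
  expect_equal(gs2$node_pct, 60)
  expect_equal(gs2$edge_pct, 75)
})

test_that("path statistics follow the disconnected-network conventions", {
  ps <- path_statistics(path3)
  expect_equal(ps$diameter, 2)
  expect_equal(ps$radius_paper, 1)
  expect_equal(ps$radius_standard, 1)
  expect_equal(ps$avg_shortest_path, (1 + 1 + 2) / 3)

  disj <- interactome(rbind(c("a", "b"), c("c", "d")))
  ps2 <- path_statistics(disj)
  expect_equal(ps2$diameter, 1)          # max over component diameters
  expect_equal(ps2$avg_shortest_path, 1) # finite pairs only

  expect_warning(ps3 <- path_statistics(interactome(nodes = c("a", "b"))),
                 "no edges")
  expect_true(all(is.na(unlist(ps3))))
})

test_that("clustering uses 2e/(k(k-1)) with degree<2 nodes counted as zero", {
  expect_equal(clustering_coefficient(tri, "a"), 1)
  expect_equal(clustering_coefficient(star3, "c"), 0)
  expect_equal(average_clustering(star3), 0)
  paw <- interactome(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                           c("c", "t")))  # triangle plus tail
  cc <- clustering_coefficient(paw)
  expect_equal(unname(cc["c"]), 2 * 1 / (3 * 2))
  expect_equal(unname(cc["t"]), 0)
  expect_equal(average_clustering(paw), mean(c(1, 1, 1 / 3, 0)))
})

test_that("summary statistics match closed forms on stars and regular graphs", {
  st <- summarize_network(star4)  # N = 5
  expect_equal(st$avg_neighbors, 8 / 5)
  expect_equal(st$density, 0.4)
  expect_equal(st$centralization, 1)

  cyc <- interactome(cbind(paste0("v", 1:6), paste0("v", c(2:6, 1))))
  stc <- summarize_network(cyc)
  expect_equal(stc$centralization, 0)
  expect_equal(stc$heterogeneity, 0)

  st3 <- summarize_network(star3)  # degrees 3,1,1,1
  expect_equal(st3$heterogeneity, sqrt(0.75) / 1.5)

  expect_warning(summarize_network(interactome(rbind(c("a", "b")))),
                 "centralization undefined")
})

test_that("path and clustering measures agree with brute-force oracles", {
  for (seed in 1:15) {
    g <- o_rand_graph(sample(10:40, 1), runif(1, 0.05, 0.25), seed = 700 + seed)
    if (!nrow(g$edges)) next
    net <- interactome(g$edges, nodes = g$nodes)
    D <- o_distances(g$nodes, g$edges)
    up <- D[upper.tri(D)]; fin <- up[is.finite(up)]
    ps <- path_statistics(net)
    expect_equal(ps$diameter, max(fin))
    expect_equal(ps$radius_paper, min(fin))
    expect_equal(ps$avg_shortest_path, mean(fin))
    giant <- o_components(g$nodes, g$edges)[[1]]
    expect_equal(ps$radius_standard,
                 if (length(giant) > 1)
                   min(apply(D[giant, giant, drop = FALSE], 1, max)) else 0)
    expect_equal(clustering_coefficient(net)[g$nodes],
                 o_clustering(g$nodes, g$edges))
  }
})
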