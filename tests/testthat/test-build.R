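recs <- function(...) {
  m <- rbind(...)
  data.frame(protein_a = m[, 1], protein_b = m[, 2],
             source = "t", evidence = m[, 3], stringsAsFactors = FALSE)
}

test_that("filtering removes predicted, self-loop and duplicate records", {
  r <- recs(c("a", "b", "experimental"), c("b", "a", "experimental"),
            c("c", "c", "experimental"), c("a", "c", "predicted"))
  out <- filter_interactions(r, exclude_predicted = TRUE)
  expect_equal(nrow(out), 1)
  expect_equal(out$protein_a, "a"); expect_equal(out$protein_b, "b")
  expect_equal(attr(out, "removed"),
               c(predicted = 1L, self_loop = 1L, duplicate = 1L))

  out2 <- filter_interactions(r, exclude_predicted = FALSE)
  expect_equal(nrow(out2), 2)  # a-b and a-c survive

  allp <- recs(c("x", "y", "predicted"))
  expect_warning(out3 <- filter_interactions(allp), "all interaction records")
  expect_equal(nrow(out3), 0)
})

test_that("one-step rule keeps seeds plus direct neighbors, excludes second shell", {
  dg <- seed_set("d1", "disease"); dt <- seed_set("t1", "drug_target")
  r <- recs(c("d1", "x", "experimental"), c("x", "t1", "experimental"),
            c("x", "y", "experimental"), c("y", "z", "experimental"))
  net <- build_integrated_network(filter_interactions(r), dg, dt)
  # y and z are two steps from every seed and must be excluded
  expect_setequal(network_nodes(net), c("d1", "t1", "x"))
  expect_equal(unname(net$role["x"]), "neighbor")
  expect_setequal(paste(network_edges(net)[, 1], network_edges(net)[, 2]),
                  c("d1 x", "t1 x"))
})

test_that("seed-seed and neighbor-neighbor edges are retained (induced subgraph)", {
  dg <- seed_set("d1", "disease"); dt <- seed_set("t1", "drug_target")
  r1 <- recs(c("d1", "x", "experimental"), c("x", "t1", "experimental"),
             c("d1", "t1", "experimental"))
  n1 <- build_integrated_network(filter_interactions(r1), dg, dt)
  expect_equal(nrow(network_edges(n1)), 3)

  r2 <- recs(c("d1", "n1", "experimental"), c("t1", "n2", "experimental"),
             c("n1", "n2", "experimental"))
  n2 <- build_integrated_network(filter_interactions(r2), dg, dt)
  expect_setequal(network_nodes(n2), c("d1", "t1", "n1", "n2"))
  # oracle: induced subgraph = all record edges with both endpoints kept
  keep <- network_nodes(n2)
  exp_edges <- r2[r2$protein_a %in% keep & r2$protein_b %in% keep, 1:2]
  expect_equal(nrow(network_edges(n2)), nrow(exp_edges))
  expect_true("n1" %in% network_edges(n2)[, 1][network_edges(n2)[, 2] == "n2"])
})

test_that("roles mark seeds, shared seeds, isolated seeds kept with warning", {
  dg <- seed_set(c("d1", "s"), "disease")
  dt <- seed_set(c("t1", "s", "ghost"), "drug_target")
  r <- recs(c("d1", "s", "experimental"), c("s", "t1", "experimental"))
  expect_warning(net <- build_integrated_network(filter_interactions(r), dg, dt),
                 "isolated")
  expect_equal(unname(net$role["s"]), "both_seed")
  expect_equal(unname(net$role["ghost"]), "drug_target_seed")
  expect_equal(igraph::degree(net$graph)[["ghost"]], 0)
  expect_error(build_integrated_network(r, character(), character()),
               "empty")
})

test_that("every non-seed node touches a seed; adding records never removes edges", {
  set.seed(42)
  for (rep in 1:20) {
    g <- o_rand_graph(30, 0.1, seed = 500 + rep)
    ev <- rep("experimental", nrow(g$edges))
    r <- data.frame(protein_a = g$edges[, 1], protein_b = g$edges[, 2],
                    source = "t", evidence = ev, stringsAsFactors = FALSE)
    dg <- seed_set(sample(g$nodes, 3), "disease")
    dt <- seed_set(sample(g$nodes, 3), "drug_target")
    net <- suppressWarnings(build_integrated_network(r, dg, dt))
    seeds <- union(dg$members, dt$members)
    nonseed <- setdiff(network_nodes(net), seeds)
    A <- o_adjacency(g$nodes, g$edges)
    for (v in nonseed)
      expect_true(any(A[v, seeds] == 1L))
    # monotonicity: appending extra records keeps all existing edges
    extra <- data.frame(protein_a = dg$members[1], protein_b = "brandnew",
                        source = "t", evidence = "experimental")
    net2 <- suppressWarnings(build_integrated_network(rbind(r, extra), dg, dt))
    e1 <- paste(network_edges(net)[, 1], network_edges(net)[, 2])
    e2 <- paste(network_edges(net2)[, 1], network_edges(net2)[, 2])
    expect_true(all(e1 %in% e2))
  }
})
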