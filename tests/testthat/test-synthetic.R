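test_that("interactome simulation is deterministic and structurally valid", {
  g1 <- simulate_interactome(100, "preferential_attachment", list(m = 2), rng_seed = 5)
  g2 <- simulate_interactome(100, "preferential_attachment", list(m = 2), rng_seed = 5)
  expect_identical(network_edges(g1), network_edges(g2))
  g3 <- simulate_interactome(100, rng_seed = 6)
  expect_false(identical(network_edges(g1), network_edges(g3)))
  validate_interactome(g1)

  # m = 1 growth yields a connected tree
  t5 <- simulate_interactome(5, "preferential_attachment", list(m = 1), rng_seed = 1)
  expect_equal(unname(network_size(t5)), c(5, 4))
  expect_length(connected_components(t5), 1)

  d1 <- simulate_interactome(80, "duplication_divergence",
                             list(p_keep = 0.4, p_anchor = 0.7), rng_seed = 9)
  d2 <- simulate_interactome(80, "duplication_divergence",
                             list(p_keep = 0.4, p_anchor = 0.7), rng_seed = 9)
  expect_identical(network_edges(d1), network_edges(d2))
  validate_interactome(d1)
  expect_error(simulate_interactome(4), "at least 5")
  expect_error(simulate_interactome(10, "duplication_divergence",
                                    list(p_keep = 2)), "probabilities")
})

test_that("preferential attachment produces hub-dominated degree distributions", {
  hits <- vapply(1:10, function(s) {
    g <- simulate_interactome(200, "preferential_attachment", list(m = 2),
                              rng_seed = 1000 + s)
    d <- degree_index(g)$degree
    max(d) > 3 * mean(d)
  }, TRUE)
  expect_true(all(hits))
})

test_that("planted bridges satisfy the mediator membership test", {
  net <- simulate_interactome(100, rng_seed = 21)
  truth <- plant_seeds_and_mediators(net, 8, 10, 3, rng_seed = 22)
  expect_length(truth$planted_mediators, 3)
  ms <- suppressWarnings(mediator_set(truth$interactome, truth$disease_seeds,
                                      truth$target_seeds))
  expect_true(all(truth$planted_mediators %in% ms$members))
  # direct membership check: planted nodes touch both classes
  el <- network_edges(truth$interactome)
  A <- o_adjacency(network_nodes(truth$interactome), el)
  for (b in truth$planted_mediators) {
    expect_true(any(A[b, truth$disease_seeds$members] == 1L))
    expect_true(any(A[b, truth$target_seeds$members] == 1L))
  }

  t0 <- plant_seeds_and_mediators(net, 8, 10, 0, rng_seed = 23)
  expect_length(t0$planted_mediators, 0)
  expect_error(plant_seeds_and_mediators(net, 60, 50, 10, rng_seed = 1),
               "infeasible")
})

test_that("annotation planting records ground truth and respects sizes", {
  net <- simulate_interactome(120, rng_seed = 31)
  truth <- plant_seeds_and_mediators(net, 8, 8, 5, rng_seed = 32)
  t1 <- plant_annotations(truth, n_terms = 1, enriched_terms = 1, effect = 10,
                          rng_seed = 33)
  expect_length(t1$annotations$term_to_genes, 1)
  expect_length(t1$planted_enriched_terms, 1)
  # effect = 1 plants nothing
  t2 <- plant_annotations(truth, n_terms = 10, enriched_terms = 2, effect = 1,
                          rng_seed = 34)
  expect_length(t2$planted_enriched_terms, 0)
  expect_length(t2$annotations$term_to_genes, 10)
  expect_true(all(lengths(t2$annotations$term_to_genes) >= 1))
})

test_that("the full synthetic truth is a pure function of its seed", {
  t1 <- paper_scale_mini(17)
  t2 <- paper_scale_mini(17)
  expect_identical(network_edges(t1$interactome), network_edges(t2$interactome))
  expect_identical(t1$disease_seeds$members, t2$disease_seeds$members)
  expect_identical(t1$planted_mediators, t2$planted_mediators)
  expect_identical(t1$annotations$term_to_genes, t2$annotations$term_to_genes)
  expect_identical(network_edges(t1$reference$graph),
                   network_edges(t2$reference$graph))
  validate_interactome(t1$interactome)
  validate_interactome(t1$reference$graph)
})

test_that("fixture files round-trip the synthetic truth byte-for-byte", {
  truth <- paper_scale_mini(8)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  f1 <- write_synthetic_fixtures(truth, d1)
  f2 <- write_synthetic_fixtures(truth, d2)
  for (k in names(f1))
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]), label = k)

  # filtering the written interaction file recovers exactly the truth graph
  rec <- read_interactions(f1[["ppi"]])
  filt <- filter_interactions(rec)
  expect_equal(unname(attr(filt, "removed")[["predicted"]]), 40)
  expect_equal(unname(attr(filt, "removed")[["duplicate"]]), 5)
  back <- interactome(cbind(filt$protein_a, filt$protein_b))
  expect_equal(network_edges(back), network_edges(truth$interactome))
  # seed lists load back through the symbol mapping
  dg <- load_seed_set(f1[["disease"]], f1[["mapping"]], "disease")
  expect_setequal(dg$members, truth$disease_seeds$members)
})
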