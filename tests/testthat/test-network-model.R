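# Network mapping, induced subgraph extraction, MCODE segmentation and
# process-graph assembly.

test_that("feature mapping reports mapped and unmapped identifiers", {
  net <- named_graph(c("A", "B", "B", "C", "C", "D"))
  expect_equal(map_to_network(c("X", "Y"), net)$n_mapped, 0)
  expect_setequal(map_to_network(c("A", "B", "C", "D"), net)$mapped,
                  c("A", "B", "C", "D"))
  ten <- c("A", "B", "C", sprintf("Z%d", 1:7))
  net2 <- named_graph(c("A", "B", "B", "C", "C", "Z1", "Z2", "Z3",
                        "Z3", "Z4"))
  mp <- map_to_network(ten, net2)   # 7 of the 10 are network nodes
  expect_equal(mp$n_mapped, 7)
  expect_equal(mp$n_unmapped, 3)
  expect_error(map_to_network("A", igraph::make_empty_graph(0)), "empty")
})

test_that("induced subgraph keeps internal edges and drops isolates", {
  # path a-b-c-d, mapped {a, c, d}: only c-d survives, a is isolated
  net <- named_graph(c("a", "b", "b", "c", "c", "d"))
  sub <- induced_feature_subgraph(c("a", "c", "d"), net)
  expect_equal(igraph::vcount(sub), 2)
  expect_setequal(igraph::V(sub)$name, c("c", "d"))
  expect_equal(attr(sub, "component_sizes"), 2)

  expect_equal(igraph::vcount(induced_feature_subgraph(c("a", "c"), net)), 0)

  tri <- named_graph(c("a", "b", "b", "c", "c", "a", "c", "d"))
  sub2 <- induced_feature_subgraph(c("a", "b", "c"), tri)
  expect_equal(igraph::ecount(sub2), 3)
})

test_that("vertex weights match closed forms on canonical graphs", {
  expect_equal(unname(mcode_vertex_weights(complete_named(4))), rep(3, 4))
  # complete-graph closed form: every K_n weight equals n - 1
  for (n in 2:8) {
    expect_equal(unname(mcode_vertex_weights(complete_named(n))),
                 rep(n - 1, n))
  }
  # star S5: center's closed neighborhood is the star, a 1-core of
  # density 2*5/(6*5) = 1/3; leaves see a single edge (density 1)
  star <- named_graph(c("c", "l1", "c", "l2", "c", "l3", "c", "l4",
                        "c", "l5"))
  w <- mcode_vertex_weights(star)
  expect_equal(unname(w["c"]), 1 / 3)
  expect_equal(unname(w[paste0("l", 1:5)]), rep(1, 5))

  iso <- named_graph(c("a", "b"), isolates = "z")
  expect_equal(unname(mcode_vertex_weights(iso)["z"]), 0)
})

test_that("weights and complexes match the brute-force oracle on random graphs", {
  set.seed(404)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    p <- runif(1, 0.2, 0.9)
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    expect_equal(mcode_vertex_weights(g), oracle_mcode_weights(g),
                 tolerance = 1e-12)
    got <- lapply(mcode_predict(g), `[[`, "members")
    want <- lapply(oracle_mcode_predict(g), `[[`, "members")
    expect_identical(got, want)
  }
})

test_that("segmentation resolves canonical fixtures", {
  # two bridged 5-cliques: the bridge lies in neither endpoint's
  # neighborhood core, so each clique is its own process
  pr <- mcode_predict(bridged_cliques(5))
  expect_length(pr, 2)
  expect_setequal(pr[[1]]$members, sprintf("V%02d", 1:5))
  expect_setequal(pr[[2]]$members, sprintf("V%02d", 6:10))

  expect_length(mcode_predict(complete_named(3)), 1)   # min_size boundary

  path6 <- named_graph(c("a", "b", "b", "c", "c", "d", "d", "e", "e", "f"))
  expect_length(mcode_predict(path6), 0)   # trees have no 2-core

  # disjointness and 2-core invariants on a composite graph
  g <- igraph::disjoint_union(bridged_cliques(4), complete_named(6, "W"))
  pr2 <- mcode_predict(g)
  mem <- unlist(lapply(pr2, `[[`, "members"))
  expect_equal(anyDuplicated(mem), 0L)
  for (p in pr2) {
    sub <- igraph::induced_subgraph(g, p$members)
    expect_gte(min(igraph::coreness(sub)), 2)
  }
})

test_that("segmentation is invariant under vertex relabeling", {
  g <- bridged_cliques(5)
  set.seed(1)
  relabel <- setNames(sprintf("Q%02d", sample(10)), igraph::V(g)$name)
  g2 <- g
  igraph::V(g2)$name <- unname(relabel[igraph::V(g)$name])
  part1 <- lapply(mcode_predict(g), function(p) sort(unname(relabel[p$members])))
  part2 <- lapply(mcode_predict(g2), function(p) sort(p$members))
  expect_setequal(vapply(part1, paste, "", collapse = ","),
                  vapply(part2, paste, "", collapse = ","))
})

test_that("process-graph edges capture concentrated cross-process wiring", {
  # three 4-cliques; all crossing edges land on the (1,2) pair
  g <- igraph::disjoint_union(complete_named(4, "A"), complete_named(4, "B"),
                              complete_named(4, "C"))
  g <- igraph::add_edges(g, c("A01", "B01", "A02", "B02", "A03", "B03"))
  procs <- mcode_predict(g)
  expect_length(procs, 3)
  model <- build_model(procs, g, name = "toy")
  expect_equal(model$total_members, 12)
  tab <- model$pair_table
  loaded <- tab$edge_count == 3
  expect_equal(sum(loaded), 1)
  expect_equal(tab$p_value[loaded], min(tab$p_value))
  # and zero-crossing pairs never form a process edge
  expect_true(all(model$process_graph$edge_count > 0))

  # single process: empty process graph
  one <- build_model(mcode_predict(complete_named(5)), complete_named(5))
  expect_equal(nrow(one$process_graph), 0)

  # overlapping processes refused
  dup <- mcode_predict(complete_named(5))
  expect_error(build_model(c(dup, dup), complete_named(5)), "disjoint")
})

test_that("cross-process significance agrees with the hypergeometric oracle", {
  g <- igraph::disjoint_union(complete_named(4, "A"), complete_named(4, "B"),
                              complete_named(4, "C"))
  g <- igraph::add_edges(g, c("A01", "B01", "A02", "B02", "A03", "B03",
                              "A04", "C01"))
  model <- build_model(mcode_predict(g), g)
  tab <- model$pair_table
  m_total <- sum(tab$edge_count)
  s_total <- sum(16, 16, 16)   # 4*4 slots per pair
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$p_value[i],
                 oracle_hyper_tail(tab$edge_count[i], 16, m_total, s_total),
                 tolerance = 1e-12)
  }
  expect_equal(tab$adjusted_p, oracle_bh(tab$p_value), tolerance = 1e-12)
})

test_that("planted modules are recovered from simulated networks", {
  sim <- simulate_network(network_sim_spec(
    200, 3, c(10L, 12L, 15L), intra_module_edge_prob = 0.8,
    background_attachment_edges = 2L, inter_module_edges = 8L, seed = 11))
  pr <- mcode_predict(sim$graph, params = mcode_params(vwp = 0.4))
  for (m in sim$membership) {
    expect_gte(best_match_jaccard(pr, m), 0.8)
  }
})
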