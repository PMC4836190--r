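# Synthetic-data generator: planted structure, class-defining PFS
# truncation, determinism, and sampling-distribution sanity.

test_that("network simulation plants the requested structure", {
  # no modules: pure preferential-attachment background, empty membership
  sim0 <- simulate_network(network_sim_spec(50, seed = 3))
  expect_length(sim0$membership, 0)
  expect_equal(igraph::vcount(sim0$graph), 50)
  expect_false(igraph::any_loop(sim0$graph))
  expect_false(igraph::any_multiple(sim0$graph))

  # p = 1 forces cliques; one inter-module edge bridges them
  spec <- network_sim_spec(10, 2, c(5L, 5L), intra_module_edge_prob = 1,
                           background_attachment_edges = 0L,
                           inter_module_edges = 1L, seed = 7)
  sim <- simulate_network(spec)
  expect_equal(igraph::ecount(sim$graph), 2 * choose(5, 2) + 1)
  for (m in sim$membership) {
    sub <- igraph::induced_subgraph(sim$graph, m)
    expect_equal(igraph::ecount(sub), choose(5, 2))   # a 5-clique
  }
  expect_equal(sort(unlist(sim$membership, use.names = FALSE)),
               sort(igraph::V(sim$graph)$name))
})

test_that("network simulation is deterministic and validates its spec", {
  spec <- network_sim_spec(200, 3, c(10L, 15L, 20L),
                           intra_module_edge_prob = 0.8, seed = 42)
  a <- simulate_network(spec)
  b <- simulate_network(spec)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_identical(a$membership, b$membership)
  # byte-identical on disk
  fa <- tempfile(); fb <- tempfile()
  write_network(a$graph, fa); write_network(b$graph, fb)
  expect_identical(readLines(fa), readLines(fb))

  expect_error(simulate_network(network_sim_spec(10, 2, c(6L, 6L))),
               "exceeds")
  expect_error(network_sim_spec(10, 1, c(2L)), "module_sizes")
  expect_error(network_sim_spec(10, 1, c(5L), intra_module_edge_prob = 1.2))
})

test_that("expression simulation reproduces effect sizes and PFS classes", {
  sig <- sprintf("F%04d", 1:10)
  spec <- expression_sim_spec(100, 100, 500, signal_features = sig,
                              effect_size = 2, seed = 11)
  st <- simulate_expression(spec)
  expect_equal(dim(st$matrix), c(500L, 200L))

  res <- st$labels == "resistant"
  for (f in sig) {
    x <- st$matrix[f, res]; y <- st$matrix[f, !res]
    smd <- (mean(x) - mean(y)) / sqrt((stats::var(x) + stats::var(y)) / 2)
    expect_gt(smd, 1.5); expect_lt(smd, 2.5)   # within +/- 0.5 of 2
  }
  # truncation contract: every resistant PFS < 12, every sensitive > 22
  expect_true(all(st$clinical$pfs_months[res] < 12))
  expect_true(all(st$clinical$pfs_months[!res] > 22))

  expect_error(expression_sim_spec(5, 5, 3, signal_features = sig),
               "subset")
})

test_that("null expression data gives calibrated two-sample tests", {
  spec <- expression_sim_spec(40, 40, 2000, effect_size = 0, seed = 5)
  st <- simulate_expression(spec)
  res <- st$labels == "resistant"
  pvals <- apply(st$matrix, 1, function(v) t.test(v[res], v[!res])$p.value)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("SL table simulation matches its spec distributionally", {
  universe <- sprintf("G%03d", 1:50)
  expect_error(simulate_sl_table(sl_sim_spec(5), character(0)), "non-empty")

  empty <- simulate_sl_table(sl_sim_spec(0), universe)
  expect_equal(nrow(empty$sl_table), 0)

  human_only <- simulate_sl_table(sl_sim_spec(30, fraction_nonhuman = 0,
                                              seed = 2), universe)
  expect_equal(nrow(human_only$orthology), 0)
  expect_true(all(human_only$sl_table$organism == "Homo sapiens"))
  expect_true(all(unlist(human_only$sl_table[, c("gene_a", "gene_b")]) %in%
                    universe))

  spec <- sl_sim_spec(600, tag_distribution = c("Synthetic Lethality" = 0.5,
                                                "Negative Genetic" = 0.3,
                                                "Positive Genetic" = 0.2),
                      seed = 9)
  sim <- simulate_sl_table(spec, universe)
  expect_equal(nrow(sim$sl_table), 600)
  observed <- table(factor(sim$sl_table$evidence_tag,
                           levels = names(spec$tag_distribution)))
  gof <- chisq.test(observed, p = spec$tag_distribution)
  expect_gt(gof$p.value, 1e-3)   # frequencies within multinomial error
  # every non-human gene is mappable back into the universe
  nh <- sim$sl_table$organism != "Homo sapiens"
  nh_genes <- unlist(sim$sl_table[nh, c("gene_a", "gene_b")])
  expect_true(all(nh_genes %in% sim$orthology$source_gene))
  expect_true(all(sim$orthology$human_gene %in% universe))
})
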