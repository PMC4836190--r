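# One-call construction of a complete synthetic input workspace: network,
# disease and drug feature sets, pathway collection, train/test expression
# studies, SL table and orthology map, plus a ready-to-run pipeline YAML.
# The defaults are the study conditions the pipeline emulates: a training
# cohort of 82 resistant / 63 sensitive and a test cohort of 29 resistant /
# 45 sensitive samples with PFS dichotomized at <12 / >22 months, three
# planted dense modules standing in for disease-relevant molecular
# processes, and drug gene sets concentrated on the leading module.

#' Simulate a ready-to-run pipeline workspace
#'
#' Writes every input file the pipeline consumes into `dir` and returns the
#' pipeline configuration (also written as `pipeline.yaml`). Ground-truth
#' structures (module membership, signal features, planted SL hits) are
#' returned for recovery tests.
#'
#' @param dir output directory (created)
#' @param seed integer master seed; all sub-generators derive from it
#' @param n_nodes network size
#' @param module_sizes planted module sizes
#' @param intra_prob within-module edge probability
#' @param n_train_resistant,n_train_sensitive training cohort class sizes
#' @param n_test_resistant,n_test_sensitive test cohort class sizes
#' @param n_signal planted differential features (drawn from module 1)
#' @param effect_size standardized mean difference of signal features
#' @param n_boot bootstrap runs configured for the classifier
#' @param n_sl_noise random SL rows added beside the planted hits
#' @return list: `config` (list, also at `dir/pipeline.yaml`), `truth`
#'   (module membership, signal features, planted SL pairs)
#' @export
simulate_workspace <- function(dir, seed = 1L, n_nodes = 400L,
                               module_sizes = c(20L, 15L, 12L),
                               intra_prob = 0.8,
                               n_train_resistant = 82L,
                               n_train_sensitive = 63L,
                               n_test_resistant = 29L,
                               n_test_sensitive = 45L,
                               n_signal = 10L, effect_size = 0.8,
                               n_boot = 200L, n_sl_noise = 40L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))

  net_spec <- network_sim_spec(
    n_background_nodes = n_nodes, n_modules = length(module_sizes),
    module_sizes = module_sizes, intra_module_edge_prob = intra_prob,
    background_attachment_edges = 2L, inter_module_edges = 12L,
    seed = seed)
  sim <- simulate_network(net_spec)
  write_network(sim$graph, p("network.tsv"))
  genes <- igraph::V(sim$graph)$name
  mods <- sim$membership
  module_genes <- unlist(mods, use.names = FALSE)
  background <- setdiff(genes, module_genes)

  set.seed(seed + 1L)
  # three overlapping disease sources emulating one literature-mined and
  # two transcriptomics-derived sets
  src <- list(
    `LIT-DISEASE` = c(module_genes, sample(background, 30)),
    `TX-META`     = c(mods[[1]], mods[[2]], sample(background, 20)),
    `TX-ATLAS`    = c(mods[[min(3, length(mods))]], sample(background, 10)))
  for (nm in names(src)) {
    writeLines(sort(unique(src[[nm]])), p(nm, ".txt"))
  }

  # drug gene sets concentrated on module 1 with private background genes
  m1 <- mods[[1]]
  drug <- list(
    drug_alpha = c(sample(m1, round(0.6 * length(m1))),
                   sample(background, 20)),
    drug_beta  = c(sample(m1, round(0.45 * length(m1))),
                   sample(background, 15)),
    drug_gamma = c(sample(m1, round(0.35 * length(m1))),
                   sample(background, 10)))
  for (nm in names(drug)) {
    writeLines(sort(unique(drug[[nm]])), p(nm, ".txt"))
  }

  # pathway collection: two pathways overlapping planted modules, the rest
  # random background sets
  pw <- list(
    PW_MODULE1_A = sample(m1, 12),
    PW_MODULE1_B = sample(m1, 8),
    PW_MODULE2   = sample(mods[[min(2, length(mods))]],
                          min(10, length(mods[[min(2, length(mods))]]))))
  for (i in 1:6) {
    pw[[sprintf("PW_RANDOM%02d", i)]] <- sample(genes, sample(15:30, 1))
  }
  write_gmt(pw, p("pathways.gmt"))

  signal <- sample(m1, n_signal)
  train_spec <- expression_sim_spec(
    n_samples_resistant = n_train_resistant,
    n_samples_sensitive = n_train_sensitive,
    n_features = length(genes), signal_features = signal,
    effect_size = effect_size, feature_ids = genes, seed = seed + 2L)
  write_expression_study(simulate_expression(train_spec),
                         p("expr_train.tsv"), p("clinical_train.tsv"))
  test_spec <- expression_sim_spec(
    n_samples_resistant = n_test_resistant,
    n_samples_sensitive = n_test_sensitive,
    n_features = length(genes), signal_features = signal,
    effect_size = effect_size,
    pfs_resistant_mean = 5.07, pfs_resistant_sd = 3.09,
    pfs_sensitive_mean = 40.21, pfs_sensitive_sd = 16.72,
    feature_ids = genes, seed = seed + 3L)
  write_expression_study(simulate_expression(test_spec),
                         p("expr_test.tsv"), p("clinical_test.tsv"))

  # SL table: two planted human synthetic-lethal pairs coupling drug_gamma
  # to drug_beta within module 1, plus random noise rows
  set.seed(seed + 4L)
  anchor <- intersect(drug$drug_gamma, m1)[1]
  partners <- setdiff(intersect(drug$drug_beta, m1), anchor)[1:2]
  planted <- data.frame(
    gene_a = anchor, gene_b = partners, organism = "Homo sapiens",
    evidence_tag = "Synthetic Lethality", stringsAsFactors = FALSE)
  noise <- simulate_sl_table(sl_sim_spec(n_sl_noise, seed = seed + 4L),
                             gene_universe = genes)
  sl_table <- rbind(planted, noise$sl_table)
  write.table(sl_table, p("sl_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(noise$orthology, p("orthology.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  config <- list(
    seed = as.integer(seed),
    outdir = file.path(dir, "results"),
    inputs = list(
      network = p("network.tsv"),
      disease_sets = lapply(setNames(names(src), names(src)),
                            function(nm) p(nm, ".txt")),
      drug_sets = lapply(setNames(names(drug), names(drug)),
                         function(nm) p(nm, ".txt")),
      pathways = p("pathways.gmt"),
      expression_train = list(expression = p("expr_train.tsv"),
                              clinical = p("clinical_train.tsv")),
      expression_test = list(expression = p("expr_test.tsv"),
                             clinical = p("clinical_test.tsv")),
      sl_table = p("sl_table.tsv"),
      orthology = p("orthology.tsv")),
    params = list(classifier = list(n_boot = as.integer(n_boot)),
                  sl = list(set_a = "drug_gamma", set_b = "drug_beta")))
  yaml::write_yaml(config, p("pipeline.yaml"))
  list(config = config,
       truth = list(membership = mods, signal_features = signal,
                    planted_sl = planted))
}
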