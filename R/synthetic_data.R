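# Synthetic-data generator: every input the pipeline consumes can be
# simulated with the statistical structure the analysis assumes — a
# scale-free background network with planted dense modules, two-class
# expression data tied to dichotomized progression-free survival, pathway
# collections overlapping the planted modules, and synthetic-lethality
# tables across organisms with an orthology map.

ORGANISMS <- c("Homo sapiens", "Saccharomyces cerevisiae", "Mus musculus",
               "Gallus gallus", "Caenorhabditis elegans",
               "Drosophila melanogaster")

#' Specification for a simulated interaction network
#'
#' The background is a preferential-attachment (scale-free) graph, the
#' choice reflecting the heavy-tailed degree distributions of real protein
#' interaction networks. Dense modules are planted on disjoint node subsets
#' as Erdos-Renyi blocks with edge probability `intra_module_edge_prob`, and
#' `inter_module_edges` additional edges run from module members to nodes
#' outside their own module.
#'
#' @param n_background_nodes total number of nodes
#' @param n_modules number of planted modules
#' @param module_sizes integer vector of module sizes, each >= 3
#' @param intra_module_edge_prob within-module edge probability in \[0, 1\]
#' @param background_attachment_edges preferential-attachment edges added per
#'   node (0 = no background edges)
#' @param inter_module_edges total number of module-to-outside edges
#' @param seed integer RNG seed
#' @return a `network_sim_spec` list
#' @export
network_sim_spec <- function(n_background_nodes, n_modules = 0L,
                             module_sizes = integer(0),
                             intra_module_edge_prob = 0.8,
                             background_attachment_edges = 2L,
                             inter_module_edges = 0L, seed = 1L) {
  stopifnot(is_count(n_background_nodes), n_background_nodes >= 1,
            is_count(n_modules), length(module_sizes) == n_modules,
            all(vapply(module_sizes, is_count, TRUE)),
            is_prob(intra_module_edge_prob),
            is_count(background_attachment_edges),
            is_count(inter_module_edges), is_count(abs(seed)))
  if (n_modules > 0 && any(module_sizes < 3)) {
    stop("module_sizes must all be >= 3")
  }
  structure(list(n_background_nodes = as.integer(n_background_nodes),
                 n_modules = as.integer(n_modules),
                 module_sizes = as.integer(module_sizes),
                 intra_module_edge_prob = intra_module_edge_prob,
                 background_attachment_edges = as.integer(background_attachment_edges),
                 inter_module_edges = as.integer(inter_module_edges),
                 seed = as.integer(seed)),
            class = "network_sim_spec")
}

#' Simulate an interaction network with planted dense modules
#'
#' @param spec a [network_sim_spec()]
#' @return list with `graph` (simple undirected `igraph` with gene-like
#'   vertex names) and `membership` (named list: module id -> member genes),
#'   the ground truth for module-recovery tests
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "network_sim_spec"))
  if (sum(spec$module_sizes) > spec$n_background_nodes) {
    stop("module_sizes sum exceeds n_background_nodes")
  }
  set.seed(spec$seed)
  n <- spec$n_background_nodes
  ids <- sprintf("G%0*d", max(4L, nchar(n)), seq_len(n))

  g <- if (spec$background_attachment_edges > 0) {
    igraph::sample_pa(n, m = spec$background_attachment_edges,
                      directed = FALSE)
  } else {
    igraph::make_empty_graph(n, directed = FALSE)
  }
  igraph::V(g)$name <- ids

  membership <- list()
  pool <- ids
  edges <- character(0)
  for (i in seq_len(spec$n_modules)) {
    mem <- sort(sample(pool, spec$module_sizes[i]))
    pool <- setdiff(pool, mem)
    membership[[sprintf("M%d", i)]] <- mem
    idx <- which(upper.tri(diag(length(mem))), arr.ind = TRUE)
    take <- runif(nrow(idx)) < spec$intra_module_edge_prob
    if (any(take)) {
      edges <- c(edges, rbind(mem[idx[take, 1]], mem[idx[take, 2]]))
    }
  }
  all_members <- unlist(membership, use.names = FALSE)
  for (k in seq_len(spec$inter_module_edges)) {
    if (length(all_members) == 0) break
    v <- sample(all_members, 1)
    own <- membership[[which(vapply(membership, function(m) v %in% m, TRUE))[1]]]
    outside <- setdiff(ids, own)
    u <- sample(outside, 1)
    edges <- c(edges, v, u)
  }
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  g <- igraph::simplify(g)
  list(graph = g, membership = membership)
}

#' Specification for a simulated two-class expression study
#'
#' Classes are defined by dichotomized progression-free survival: resistant
#' samples draw PFS from a truncated normal on (0, 12) months, sensitive
#' samples on (22, Inf). The default PFS moments (8.13 +/- 2.77 resistant,
#' 39.33 +/- 22.40 sensitive) match the training-cohort clinical
#' characteristics the pipeline targets. Signal features differ between
#' classes by `effect_size` standard deviations; all other features are
#' standard normal in both classes.
#'
#' @param n_samples_resistant,n_samples_sensitive class sizes
#' @param n_features number of features (probes/genes)
#' @param signal_features identifiers of differential features (subset of
#'   `feature_ids`)
#' @param effect_size standardized mean difference (>= 0) added to the
#'   resistant class for signal features
#' @param pfs_resistant_mean,pfs_resistant_sd months, truncated to (0, 12)
#' @param pfs_sensitive_mean,pfs_sensitive_sd months, truncated to (22, Inf)
#' @param feature_ids optional feature identifier universe (defaults to
#'   `F0001`, ...); length must equal `n_features`
#' @param seed integer RNG seed
#' @return an `expression_sim_spec` list
#' @export
expression_sim_spec <- function(n_samples_resistant, n_samples_sensitive,
                                n_features, signal_features = character(0),
                                effect_size = 1,
                                pfs_resistant_mean = 8.13,
                                pfs_resistant_sd = 2.77,
                                pfs_sensitive_mean = 39.33,
                                pfs_sensitive_sd = 22.40,
                                feature_ids = NULL, seed = 1L) {
  stopifnot(is_count(n_samples_resistant), is_count(n_samples_sensitive),
            is_count(n_features), effect_size >= 0)
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("F%0*d", max(4L, nchar(n_features)),
                           seq_len(n_features))
  }
  if (length(feature_ids) != n_features) {
    stop("feature_ids length must equal n_features")
  }
  if (!all(signal_features %in% feature_ids)) {
    stop("signal_features must be a subset of the feature universe")
  }
  structure(list(n_samples_resistant = as.integer(n_samples_resistant),
                 n_samples_sensitive = as.integer(n_samples_sensitive),
                 n_features = as.integer(n_features),
                 signal_features = signal_features,
                 effect_size = effect_size,
                 pfs_resistant_mean = pfs_resistant_mean,
                 pfs_resistant_sd = pfs_resistant_sd,
                 pfs_sensitive_mean = pfs_sensitive_mean,
                 pfs_sensitive_sd = pfs_sensitive_sd,
                 feature_ids = feature_ids,
                 seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' Simulate a two-class expression study with PFS-defined classes
#'
#' @param spec an [expression_sim_spec()]
#' @return an [expression_study()] with `labels` set and the planted signal
#'   features recorded in `attr(, "signal_features")`
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_sim_spec"))
  set.seed(spec$seed)
  nr <- spec$n_samples_resistant
  ns <- spec$n_samples_sensitive
  n <- nr + ns
  sample_ids <- sprintf("S%0*d", max(3L, nchar(n)), seq_len(n))
  labels <- c(rep("resistant", nr), rep("sensitive", ns))

  mat <- matrix(rnorm(spec$n_features * n), nrow = spec$n_features,
                dimnames = list(spec$feature_ids, sample_ids))
  if (length(spec$signal_features) > 0 && spec$effect_size > 0 && nr > 0) {
    mat[spec$signal_features, labels == "resistant"] <-
      mat[spec$signal_features, labels == "resistant"] + spec$effect_size
  }
  pfs <- numeric(n)
  pfs[labels == "resistant"] <- rtruncnorm(nr, spec$pfs_resistant_mean,
                                           spec$pfs_resistant_sd, 0, 12)
  pfs[labels == "sensitive"] <- rtruncnorm(ns, spec$pfs_sensitive_mean,
                                           spec$pfs_sensitive_sd, 22, Inf)
  clin <- data.frame(sample_id = sample_ids, pfs_months = pfs,
                     stringsAsFactors = FALSE)
  study <- expression_study(mat, clin, labels = labels)
  attr(study, "signal_features") <- spec$signal_features
  study
}

#' Specification for a simulated synthetic-lethality table
#'
#' @param n_pairs number of interaction rows
#' @param organisms organism labels to draw from (first taken as human when
#'   it equals `"Homo sapiens"`); defaults to the six organisms screened
#' @param tag_distribution named probability vector over evidence tags
#'   (must sum to 1)
#' @param fraction_nonhuman probability that a row comes from a non-human
#'   organism
#' @param seed integer RNG seed
#' @return an `sl_sim_spec` list
#' @export
sl_sim_spec <- function(n_pairs, organisms = ORGANISMS,
                        tag_distribution = c("Synthetic Lethality" = 0.45,
                                             "Negative Genetic" = 0.45,
                                             "Positive Genetic" = 0.10),
                        fraction_nonhuman = 0.3, seed = 1L) {
  stopifnot(is_count(n_pairs), length(organisms) >= 1,
            !is.null(names(tag_distribution)),
            all(tag_distribution >= 0),
            abs(sum(tag_distribution) - 1) < 1e-8,
            is_prob(fraction_nonhuman))
  structure(list(n_pairs = as.integer(n_pairs), organisms = organisms,
                 tag_distribution = tag_distribution,
                 fraction_nonhuman = fraction_nonhuman,
                 seed = as.integer(seed)),
            class = "sl_sim_spec")
}

#' Simulate a synthetic-lethality interaction table and orthology map
#'
#' Human rows pair genes drawn from `gene_universe`. Non-human rows use
#' organism-prefixed source identifiers, each of which is given an orthology
#' row mapping it back into `gene_universe`, so humanization of the emitted
#' table always succeeds.
#'
#' @param spec an [sl_sim_spec()]
#' @param gene_universe non-empty character vector of human gene identifiers
#' @return list with `sl_table` (gene_a, gene_b, organism, evidence_tag) and
#'   `orthology` (organism, source_gene, human_gene)
#' @export
simulate_sl_table <- function(spec, gene_universe) {
  stopifnot(inherits(spec, "sl_sim_spec"))
  if (length(gene_universe) == 0) stop("gene_universe must be non-empty")
  set.seed(spec$seed)
  nonhuman <- setdiff(spec$organisms, "Homo sapiens")
  if (length(nonhuman) == 0) nonhuman <- NULL

  n <- spec$n_pairs
  if (n == 0L) {
    return(list(sl_table = data.frame(gene_a = character(0),
                                      gene_b = character(0),
                                      organism = character(0),
                                      evidence_tag = character(0)),
                orthology = data.frame(organism = character(0),
                                       source_gene = character(0),
                                       human_gene = character(0))))
  }
  is_nonhuman <- if (is.null(nonhuman)) rep(FALSE, n) else
    runif(n) < spec$fraction_nonhuman
  org <- ifelse(is_nonhuman,
                sample(c(nonhuman, nonhuman), n, replace = TRUE),
                "Homo sapiens")
  tag <- sample(names(spec$tag_distribution), n, replace = TRUE,
                prob = spec$tag_distribution)

  gene_a <- character(n); gene_b <- character(n)
  orth <- list()
  prefix <- function(o) gsub("[^A-Za-z]", "", abbreviate(o, 2))
  for (i in seq_len(n)) {
    if (org[i] == "Homo sapiens") {
      gg <- sample(gene_universe, 2,
                   replace = length(gene_universe) < 2)
      gene_a[i] <- gg[1]; gene_b[i] <- gg[2]
    } else {
      src <- sprintf("%s_%04da", prefix(org[i]), i)
      src2 <- sprintf("%s_%04db", prefix(org[i]), i)
      gene_a[i] <- src; gene_b[i] <- src2
      hg <- sample(gene_universe, 2, replace = length(gene_universe) < 2)
      orth[[length(orth) + 1L]] <- data.frame(
        organism = org[i], source_gene = c(src, src2), human_gene = hg,
        stringsAsFactors = FALSE)
    }
  }
  orthology <- if (length(orth) > 0) do.call(rbind, orth) else
    data.frame(organism = character(0), source_gene = character(0),
               human_gene = character(0))
  list(sl_table = data.frame(gene_a = gene_a, gene_b = gene_b,
                             organism = org, evidence_tag = tag,
                             stringsAsFactors = FALSE),
       orthology = orthology)
}
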