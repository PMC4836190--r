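# Molecular model assembly: feature-set-to-network mapping, induced
# subgraph extraction, and the process-level graph whose edges mark pairs
# of molecular processes sharing significantly many interactions.

#' Map a feature set onto an interaction network
#'
#' @param fs a [feature_set()] or character vector of gene identifiers
#' @param net undirected `igraph` with vertex names
#' @return list with `mapped` (features that are network nodes), `unmapped`,
#'   and the two counts
#' @export
map_to_network <- function(fs, net) {
  if (inherits(fs, "feature_set")) fs <- fs$features
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0) stop("network is empty")
  nodes <- igraph::V(net)$name
  mapped <- intersect(fs, nodes)
  unmapped <- setdiff(fs, nodes)
  list(mapped = mapped, unmapped = unmapped,
       n_mapped = length(mapped), n_unmapped = length(unmapped))
}

#' Extract the induced subgraph of a mapped feature set
#'
#' Restricts the network to the given genes, keeps only edges with both
#' endpoints in the set, and removes isolated vertices — every retained
#' feature interacts with at least one other feature of the set. Connected
#' component sizes are reported in `attr(, "component_sizes")`.
#'
#' @param genes character vector of mapped gene identifiers
#' @param net undirected `igraph`
#' @return undirected `igraph`
#' @export
induced_feature_subgraph <- function(genes, net) {
  genes <- intersect(genes, igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, genes)
  iso <- igraph::V(sub)[igraph::degree(sub) == 0]
  sub <- igraph::delete_vertices(sub, iso)
  comp <- igraph::components(sub)
  attr(sub, "component_sizes") <- sort(comp$csize, decreasing = TRUE)
  sub
}

#' Assemble a molecular model from disjoint processes
#'
#' For every pair of processes the number of network edges crossing the
#' pair is counted and tested for over-representation against the null
#' that cross-process edges land on a pair proportionally to the product
#' of the process sizes among all cross-pair vertex slots (one-sided
#' hypergeometric). P-values are Benjamini-Hochberg adjusted across pairs;
#' pairs with adjusted p below `alpha` form the process-level graph.
#'
#' @param processes list of `molecular_process` objects (pairwise disjoint)
#' @param net undirected `igraph` supplying the cross-process edges
#' @param name model label
#' @param alpha adjusted-p threshold for process-graph edges
#' @return a `molecular_model`: processes, `process_graph` (significant
#'   pairs), `pair_table` (all pairs with counts and p-values) and
#'   `total_members`
#' @export
build_model <- function(processes, net, name = "model", alpha = 0.05) {
  members <- lapply(processes, `[[`, "members")
  all_mem <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_mem)) stop("processes must be pairwise disjoint")
  np <- length(processes)
  ids <- vapply(processes, `[[`, 1L, "process_id")

  empty <- data.frame(process_a = integer(0), process_b = integer(0),
                      edge_count = integer(0), p_value = numeric(0),
                      adjusted_p = numeric(0))
  if (np < 2) {
    return(structure(list(name = name, processes = processes,
                          process_graph = empty, pair_table = empty,
                          total_members = length(all_mem)),
                     class = "molecular_model"))
  }
  lookup <- setNames(rep(ids, lengths(members)), all_mem)
  el <- igraph::as_edgelist(net)
  pa <- lookup[el[, 1]]
  pb <- lookup[el[, 2]]
  cross <- !is.na(pa) & !is.na(pb) & pa != pb
  m_total <- sum(cross)

  pairs <- t(utils::combn(sort(ids), 2))
  sizes <- setNames(lengths(members), ids)
  slots <- sizes[as.character(pairs[, 1])] * sizes[as.character(pairs[, 2])]
  s_total <- sum(slots)
  key <- paste(pmin(pa[cross], pb[cross]), pmax(pa[cross], pb[cross]))
  counts_tab <- table(key)
  pk <- paste(pairs[, 1], pairs[, 2])
  counts <- as.integer(counts_tab[pk])
  counts[is.na(counts)] <- 0L

  p <- phyper(counts - 1, slots, s_total - slots, m_total,
              lower.tail = FALSE)
  adj <- p.adjust(p, method = "BH")
  pair_table <- data.frame(process_a = pairs[, 1], process_b = pairs[, 2],
                           edge_count = counts, p_value = p,
                           adjusted_p = adj)
  process_graph <- pair_table[pair_table$adjusted_p < alpha &
                                pair_table$edge_count > 0, , drop = FALSE]
  rownames(process_graph) <- NULL
  structure(list(name = name, processes = processes,
                 process_graph = process_graph, pair_table = pair_table,
                 total_members = length(all_mem)),
            class = "molecular_model")
}

#' Full model derivation: map, induce, segment, assemble
#'
#' Convenience wrapper running the whole derivation of a molecular model
#' from a feature set and a network. The induced subgraph is segmented as a
#' whole (it is not reduced to its largest component); component sizes are
#' available on the induced subgraph.
#'
#' @param fs [feature_set()] or character vector
#' @param net undirected `igraph`
#' @param params [mcode_params()]
#' @param name model label
#' @param alpha process-graph significance threshold
#' @return a `molecular_model`; the mapping report and induced subgraph are
#'   attached as attributes `mapping` and `subgraph`
#' @export
derive_model <- function(fs, net, params = mcode_params(), name = "model",
                         alpha = 0.05) {
  mp <- map_to_network(fs, net)
  sub <- induced_feature_subgraph(mp$mapped, net)
  procs <- mcode_predict(sub, params = params)
  model <- build_model(procs, net, name = name, alpha = alpha)
  attr(model, "mapping") <- mp
  attr(model, "subgraph") <- sub
  model
}

#' All member genes of a molecular model
#' @param model a `molecular_model`
#' @return character vector (sorted, unique)
#' @export
model_members <- function(model) {
  sort(unique(unlist(lapply(model$processes, `[[`, "members"))))
}

#' @export
print.molecular_model <- function(x, ...) {
  cat(sprintf("<molecular_model> %s: %d processes, %d members, %d process-graph edges\n",
              x$name, length(x$processes), x$total_members,
              nrow(x$process_graph)))
  invisible(x)
}
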