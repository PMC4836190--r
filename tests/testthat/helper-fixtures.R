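# Shared fixture builders; all fixtures are generated in code.

# undirected named graph from a flat vertex-pair vector
named_graph <- function(edges, isolates = character(0)) {
  g <- igraph::make_graph(edges, directed = FALSE)
  if (length(isolates) > 0) g <- igraph::add_vertices(g, length(isolates),
                                                      name = isolates)
  g
}

# two k-cliques joined by a single bridge edge V01-V(k+1)
bridged_cliques <- function(k = 5) {
  g <- igraph::disjoint_union(igraph::make_full_graph(k),
                              igraph::make_full_graph(k))
  igraph::V(g)$name <- sprintf("V%02d", seq_len(2 * k))
  igraph::add_edges(g, c("V01", sprintf("V%02d", k + 1)))
}

complete_named <- function(n, prefix = "K") {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- sprintf("%s%02d", prefix, seq_len(n))
  g
}

# a small labeled study built directly (no generator) for exact checks
tiny_study <- function(pfs, mat = NULL, features = NULL) {
  n <- length(pfs)
  ids <- sprintf("S%02d", seq_len(n))
  if (is.null(mat)) {
    if (is.null(features)) features <- c("FA", "FB", "FC")
    mat <- matrix(seq_len(length(features) * n), nrow = length(features),
                  dimnames = list(features, ids))
  } else {
    colnames(mat) <- ids
  }
  expression_study(mat, data.frame(sample_id = ids, pfs_months = pfs))
}

# synthetic stand-in clinical tables carrying the printed cohort margins
# (n_below samples < 12 months, n_above > 22, remainder in between)
synthetic_cohort_pfs <- function(n_below, n_above, n_mid, seed) {
  set.seed(seed)
  c(rtruncnorm(n_below, 8.13, 2.77, 0, 12),
    rtruncnorm(n_mid, 17, 3, 12, 22),
    rtruncnorm(n_above, 39.33, 22.40, 22, Inf))
}

# write a character vector to a temp file, returning the path
tmp_lines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

best_match_jaccard <- function(processes, module) {
  if (length(processes) == 0) return(0)
  max(vapply(processes, function(p) {
    length(intersect(p$members, module)) /
      length(union(p$members, module))
  }, 0))
}
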