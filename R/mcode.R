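# Molecular Complex Detection (MCODE-style) graph segmentation.
#
# Vertex weighting: for each vertex the highest k-core of its closed
# neighborhood is found; the weight is that core number times the density
# of the core subgraph (density = 2E / (V(V-1))). Complex prediction seeds
# at the highest-weight unassigned vertex and expands breadth-first,
# admitting unassigned neighbors whose weight exceeds
# seed_weight * (1 - vwp) and reached along an edge lying inside the
# closed-neighborhood highest k-core of either endpoint — the latter
# constraint keeps sparse bridges between dense regions from merging
# complexes, since a bridge belongs to neither endpoint's neighborhood
# core. Post-processing
# drops complexes lacking a 2-core, optionally trims degree-1 members
# (haircut) and adds dense boundary vertices (fluff), and discards
# complexes below the minimum size.

#' MCODE parameter set
#'
#' @param vwp vertex weight percentage in \[0, 1\]: expansion admits
#'   neighbors with weight > seed_weight * (1 - vwp)
#' @param haircut iteratively remove degree-1 complex members
#' @param fluff add unassigned boundary vertices whose closed-neighborhood
#'   density exceeds `fluff_threshold`
#' @param fluff_threshold density in \[0, 1\]
#' @param min_size minimum complex size retained
#' @return an `mcode_params` list
#' @export
mcode_params <- function(vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluff_threshold = 0.2, min_size = 3L) {
  stopifnot(is_prob(vwp), is.logical(haircut), is.logical(fluff),
            is_prob(fluff_threshold), is_count(min_size), min_size >= 1)
  structure(list(vwp = vwp, haircut = haircut, fluff = fluff,
                 fluff_threshold = fluff_threshold,
                 min_size = as.integer(min_size)),
            class = "mcode_params")
}

# adjacency as a named list of character vectors, the workhorse structure
adjacency_list <- function(g) {
  nm <- igraph::V(g)$name
  al <- igraph::as_adj_list(g, mode = "all")
  setNames(lapply(al, function(v) nm[as.integer(v)]), nm)
}

# highest k-core of the subgraph induced on `verts`: returns list(k, members)
# k = 0 with all members when the induced subgraph has no edges
highest_kcore <- function(adj, verts) {
  if (length(verts) < 2) return(list(k = 0L, members = verts))
  deg <- vapply(verts, function(v) sum(adj[[v]] %in% verts), 1L)
  names(deg) <- verts
  cur <- verts
  best_k <- 0L
  best <- verts
  k <- 1L
  repeat {
    # prune vertices of degree < k until stable
    repeat {
      low <- cur[deg[cur] < k]
      if (length(low) == 0) break
      cur <- setdiff(cur, low)
      if (length(cur) == 0) break
      deg[cur] <- vapply(cur, function(v) sum(adj[[v]] %in% cur), 1L)
    }
    if (length(cur) == 0) break
    best_k <- k
    best <- cur
    k <- k + 1L
  }
  list(k = best_k, members = best)
}

graph_density_of <- function(adj, verts) {
  nv <- length(verts)
  if (nv < 2) return(0)
  ne <- sum(vapply(verts, function(v) sum(adj[[v]] %in% verts), 1L)) / 2
  2 * ne / (nv * (nv - 1))
}

# per-vertex weight + the members of the closed-neighborhood highest k-core
mcode_vertex_info <- function(g) {
  stopifnot(igraph::is_igraph(g), !igraph::is_directed(g))
  adj <- adjacency_list(g)
  nm <- names(adj)
  info <- lapply(nm, function(v) {
    nb <- c(v, adj[[v]])
    core <- highest_kcore(adj, nb)
    if (core$k == 0L) {
      list(weight = 0, k = 0L, core = character(0))
    } else {
      list(weight = core$k * graph_density_of(adj, core$members),
           k = core$k, core = core$members)
    }
  })
  names(info) <- nm
  info
}

#' MCODE vertex weights
#'
#' Weight of a vertex = (highest k-core number of its closed neighborhood)
#' times (density of that k-core subgraph). Isolated vertices weigh 0;
#' every vertex of the complete graph K_n weighs n - 1.
#'
#' @param g simple undirected `igraph` with vertex names
#' @return named numeric vector of weights
#' @export
mcode_vertex_weights <- function(g) {
  info <- mcode_vertex_info(g)
  vapply(info, `[[`, 0, "weight")
}

#' MCODE complex prediction
#'
#' Segments a graph into disjoint dense complexes ("molecular processes").
#' Seeds are taken in order of (weight desc, degree desc, lexicographic
#' name); expansion and post-processing are fully deterministic.
#'
#' @param g simple undirected `igraph` with vertex names
#' @param weights optional precomputed [mcode_vertex_weights()] (recomputed
#'   when `NULL`)
#' @param params an [mcode_params()]
#' @return list of `molecular_process` objects, ordered by score (mean
#'   member weight) descending and numbered from 1
#' @export
mcode_predict <- function(g, weights = NULL, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  info <- mcode_vertex_info(g)
  w <- vapply(info, `[[`, 0, "weight")
  if (!is.null(weights)) {
    stopifnot(setequal(names(weights), names(w)))
    w <- weights[names(w)]
  }
  adj <- adjacency_list(g)
  deg <- vapply(adj, length, 1L)
  nm <- names(w)
  ord <- nm[order(-w, -deg, nm)]

  assigned <- setNames(rep(FALSE, length(nm)), nm)
  raw <- list()
  for (s in ord) {
    if (assigned[[s]]) next
    thr <- w[[s]] * (1 - params$vwp)
    members <- s
    assigned[[s]] <- TRUE
    queue <- s
    while (length(queue) > 0) {
      x <- queue[1]
      queue <- queue[-1]
      nb <- adj[[x]]
      # an edge supports expansion only when it lies inside a dense
      # (order >= 2) closed-neighborhood core of one of its endpoints
      supported <- (info[[x]]$k >= 2L & nb %in% info[[x]]$core) |
        vapply(nb, function(y) info[[y]]$k >= 2L && x %in% info[[y]]$core,
               TRUE)
      cand <- nb[supported]
      cand <- cand[!assigned[cand]]
      cand <- cand[w[cand] >= thr]   # excluded only when deviation exceeds vwp
      if (length(cand) == 0) next
      cand <- cand[order(-w[cand], -deg[cand], cand)]
      assigned[cand] <- TRUE
      members <- c(members, cand)
      queue <- c(queue, cand)
    }
    raw[[length(raw) + 1L]] <- list(seed = s, members = members)
  }

  procs <- list()
  for (cx in raw) {
    mem <- cx$members
    core2 <- highest_kcore(adj, mem)
    if (core2$k < 2L) next                       # complex lacks a 2-core
    if (params$haircut) {
      repeat {
        d <- vapply(mem, function(v) sum(adj[[v]] %in% mem), 1L)
        low <- mem[d <= 1]
        if (length(low) == 0) break
        mem <- setdiff(mem, low)
      }
    }
    if (params$fluff) {
      boundary <- setdiff(unique(unlist(adj[mem], use.names = FALSE)), mem)
      boundary <- boundary[!assigned[boundary]]
      add <- boundary[vapply(boundary, function(v) {
        graph_density_of(adj, c(v, adj[[v]])) > params$fluff_threshold
      }, TRUE)]
      if (length(add) > 0) {
        assigned[add] <- TRUE
        mem <- c(mem, add)
      }
    }
    if (length(mem) < params$min_size) next
    mem <- sort(mem)
    internal <- do.call(rbind, lapply(mem, function(v) {
      nb <- intersect(adj[[v]], mem)
      nb <- nb[nb > v]
      if (length(nb) == 0) NULL else cbind(v, nb)
    }))
    procs[[length(procs) + 1L]] <- structure(
      list(process_id = NA_integer_, members = mem,
           internal_edges = internal, seed_vertex = cx$seed,
           score = mean(w[mem])),
      class = "molecular_process")
  }
  if (length(procs) == 0) return(procs)
  score <- vapply(procs, `[[`, 0, "score")
  size <- vapply(procs, function(p) length(p$members), 1L)
  first <- vapply(procs, function(p) p$members[1], "")
  o <- order(-score, -size, first)
  procs <- procs[o]
  for (i in seq_along(procs)) procs[[i]]$process_id <- i
  procs
}

#' @export
print.molecular_process <- function(x, ...) {
  cat(sprintf("<molecular_process %s> %d members, seed %s, score %.3f\n",
              x$process_id, length(x$members), x$seed_vertex, x$score))
  invisible(x)
}
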