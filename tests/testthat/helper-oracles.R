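# Independent brute-force oracles used to validate the package's
# implementations. Everything here works on plain adjacency matrices with
# repeated-pruning k-core computation and explicit enumeration; none of it
# calls the package's own code paths.

# adjacency matrix with dimnames from an igraph
adj_matrix_of <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  A[A > 1] <- 1
  diag(A) <- 0
  A
}

# highest k-core of the subgraph induced on `verts` by repeated pruning:
# for k = 1, 2, ... delete vertices of induced degree < k until stable;
# the last k with survivors wins. Returns list(k, members).
oracle_highest_core <- function(A, verts) {
  if (length(verts) < 2) return(list(k = 0L, members = verts))
  best_k <- 0L
  best <- verts
  k <- 1L
  repeat {
    cur <- verts
    repeat {
      if (length(cur) == 0) break
      deg <- rowSums(A[cur, cur, drop = FALSE])
      drop <- cur[deg < k]
      if (length(drop) == 0) break
      cur <- setdiff(cur, drop)
    }
    if (length(cur) == 0) break
    best_k <- k
    best <- cur
    k <- k + 1L
  }
  list(k = best_k, members = best)
}

oracle_density <- function(A, verts) {
  nv <- length(verts)
  if (nv < 2) return(0)
  ne <- sum(A[verts, verts]) / 2
  2 * ne / (nv * (nv - 1))
}

# MCODE vertex weights by repeated-pruning core enumeration
oracle_mcode_weights <- function(g) {
  A <- adj_matrix_of(g)
  nm <- rownames(A)
  w <- setNames(numeric(length(nm)), nm)
  for (v in nm) {
    nb <- c(v, nm[A[v, ] == 1])
    core <- oracle_highest_core(A, nb)
    w[v] <- if (core$k == 0) 0 else core$k * oracle_density(A, core$members)
  }
  w
}

# Independent complex prediction mirroring the documented contract via a
# recursive depth-first expansion over an adjacency matrix.
oracle_mcode_predict <- function(g, vwp = 0.2, haircut = TRUE,
                                 min_size = 3L) {
  A <- adj_matrix_of(g)
  nm <- rownames(A)
  info <- lapply(setNames(nm, nm), function(v) {
    oracle_highest_core(A, c(v, nm[A[v, ] == 1]))
  })
  w <- vapply(nm, function(v) {
    if (info[[v]]$k == 0) 0 else
      info[[v]]$k * oracle_density(A, info[[v]]$members)
  }, 0)
  deg <- rowSums(A)
  seeds <- nm[order(-w, -deg, nm)]
  assigned <- setNames(rep(FALSE, length(nm)), nm)
  edge_ok <- function(x, y) {
    (info[[x]]$k >= 2 && y %in% info[[x]]$members) ||
      (info[[y]]$k >= 2 && x %in% info[[y]]$members)
  }
  complexes <- list()
  for (s in seeds) {
    if (assigned[[s]]) next
    thr <- w[[s]] * (1 - vwp)
    members <- character(0)
    grow <- function(x) {
      assigned[[x]] <<- TRUE
      members <<- c(members, x)
      nb <- nm[A[x, ] == 1]
      nb <- nb[!assigned[nb] & w[nb] >= thr &
                 vapply(nb, edge_ok, TRUE, x = x)]
      nb <- nb[order(-w[nb], -deg[nb], nb)]
      for (y in nb) if (!assigned[[y]]) grow(y)
    }
    grow(s)
    complexes[[length(complexes) + 1L]] <- list(seed = s, members = members)
  }
  out <- list()
  for (cx in complexes) {
    mem <- cx$members
    if (oracle_highest_core(A, mem)$k < 2) next
    if (haircut) {
      repeat {
        d <- rowSums(A[mem, mem, drop = FALSE])
        low <- mem[d <= 1]
        if (length(low) == 0) break
        mem <- setdiff(mem, low)
      }
    }
    if (length(mem) < min_size) next
    out[[length(out) + 1L]] <- list(members = sort(mem),
                                    score = mean(w[mem]), seed = cx$seed)
  }
  if (length(out) == 0) return(out)
  score <- vapply(out, `[[`, 0, "score")
  size <- vapply(out, function(p) length(p$members), 1L)
  first <- vapply(out, function(p) p$members[1], "")
  out[order(-score, -size, first)]
}

# The oracle traversal is depth-first while the implementation is
# breadth-first; both admit exactly the vertices reachable through
# admissible edges with weight >= threshold, so the member sets must agree.

# all-pairs ROC AUC with explicit 0.5 tie credit
oracle_auc_allpairs <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# upper hypergeometric tail P(X >= k) by explicit binomial-coefficient sums
oracle_hyper_tail <- function(k, K, n, N) {
  jmax <- min(n, K)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# textbook Pearson correlation: covariance over product of sds
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Benjamini-Hochberg step-up by the direct definition:
# adj_i = min over j with p_j >= p_i (in sorted order, j >= rank_i) of
# p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, 0)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}
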