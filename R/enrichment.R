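# Pathway over-representation analysis: one-sided Fisher/hypergeometric
# test of a query gene list against each pathway of a collection, with
# Benjamini-Hochberg adjustment. The "estimate" column is the percentage
# of the query list falling in the pathway, reported to 2 decimals.

#' Construct a pathway collection
#'
#' @param pathways named list of gene-identifier vectors (e.g. from
#'   [read_gmt()])
#' @param background gene universe; defaults to the union of all pathways.
#'   Pathway sets are restricted to the background; pathways empty after
#'   restriction are dropped.
#' @return a `pathway_collection`
#' @export
pathway_collection <- function(pathways, background = NULL) {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  pathways <- lapply(pathways, function(p) unique(as.character(p)))
  if (is.null(background)) {
    background <- unique(unlist(pathways, use.names = FALSE))
  }
  background <- unique(as.character(background))
  if (length(background) == 0) stop("background must be non-empty")
  pathways <- lapply(pathways, intersect, y = background)
  pathways <- pathways[lengths(pathways) > 0]
  structure(list(pathways = pathways, background = background),
            class = "pathway_collection")
}

#' Over-representation analysis of a gene list
#'
#' Per pathway, the one-sided hypergeometric (Fisher exact) p-value of the
#' 2x2 table (query-in-pathway, query-outside, pathway-remainder, rest of
#' background). Pathways overlapping the query in fewer than `min_overlap`
#' genes are reported untested (`p_raw = NA`) and excluded from the
#' Benjamini-Hochberg adjustment. The optional EASE variant scores the
#' table with one overlap gene removed, a conservative penalization used
#' by the DAVID web tool; it is off by default.
#'
#' @param query character vector of gene identifiers (non-empty); genes
#'   outside the background are dropped with a warning
#' @param collection a [pathway_collection()]
#' @param min_overlap minimum query-pathway overlap tested (default 2)
#' @param ease use the EASE-score variant (k - 1)
#' @return data.frame sorted by adjusted p: pathway_id,
#'   n_list_genes_in_pathway, estimate (percent of query, 2 decimals),
#'   p_raw, p_adjusted
#' @export
enrich <- function(query, collection, min_overlap = 2L, ease = FALSE) {
  stopifnot(inherits(collection, "pathway_collection"))
  query <- unique(as.character(query))
  if (length(query) == 0) stop("query must be non-empty")
  outside <- setdiff(query, collection$background)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside background dropped")
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop("no query genes left within the background")
  n <- length(query)
  N <- length(collection$background)
  rows <- lapply(names(collection$pathways), function(pid) {
    pw <- collection$pathways[[pid]]
    k <- length(intersect(query, pw))
    K <- length(pw)
    p <- NA_real_
    if (k >= min_overlap) {
      keff <- if (ease) max(k - 1L, 0L) else k
      p <- phyper(keff - 1, K, N - K, n, lower.tail = FALSE)
    }
    data.frame(pathway_id = pid, n_list_genes_in_pathway = k,
               estimate = round(100 * k / n, 2), p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  tested <- !is.na(out$p_raw)
  out$p_adjusted[tested] <- bh_adjust(out$p_raw[tested])
  out <- out[order(is.na(out$p_adjusted), out$p_adjusted, out$p_raw,
                   out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up adjusted p-values with monotonicity enforcement;
#' the input order is preserved.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
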