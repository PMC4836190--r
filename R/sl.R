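# Synthetic-lethality screening: filter curated interaction tables by
# evidence tag and organism, transfer non-human pairs to human genes via
# orthology (cartesian expansion over one-to-many mappings), and screen
# for pairs linking two drug models within a disease process.

SL_TAGS <- c("Synthetic Lethality", "Negative Genetic")

#' Humanize a synthetic-lethality interaction table
#'
#' Rows are filtered to the allowed evidence tags and organisms. Human rows
#' pass through; each non-human endpoint is expanded to all of its mapped
#' human genes (cartesian product over both endpoints). Self-pairs are
#' dropped and pairs are deduplicated as unordered, keeping per-pair
#' source-organism provenance. Rows with an unmappable non-human endpoint
#' are dropped and counted.
#'
#' @param sl_table data.frame with columns gene_a, gene_b, organism,
#'   evidence_tag (see [read_sl_table()])
#' @param orthology data.frame with columns source_gene, human_gene and
#'   optionally organism; `NULL` is allowed when all rows are human
#' @param allowed_tags evidence tags retained (default the two
#'   synthetic-lethality tags)
#' @param allowed_organisms organisms retained (default the six screened)
#' @return data.frame of unordered human pairs: gene_a, gene_b (gene_a <
#'   gene_b), organisms (semicolon-joined provenance), n_source_rows;
#'   dropped-row count in `attr(, "n_dropped")`
#' @export
humanize_sl <- function(sl_table, orthology = NULL,
                        allowed_tags = SL_TAGS,
                        allowed_organisms = ORGANISMS) {
  need <- c("gene_a", "gene_b", "organism", "evidence_tag")
  stopifnot(all(need %in% names(sl_table)))
  tab <- sl_table[sl_table$evidence_tag %in% allowed_tags &
                    sl_table$organism %in% allowed_organisms, , drop = FALSE]
  lookup <- function(gene, organism) {
    if (organism == "Homo sapiens") return(gene)
    if (is.null(orthology)) return(character(0))
    hit <- orthology$source_gene == gene
    if ("organism" %in% names(orthology)) {
      hit <- hit & orthology$organism == organism
    }
    unique(orthology$human_gene[hit])
  }
  pairs <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(tab))) {
    ha <- lookup(tab$gene_a[i], tab$organism[i])
    hb <- lookup(tab$gene_b[i], tab$organism[i])
    if (length(ha) == 0 || length(hb) == 0) {
      n_dropped <- n_dropped + 1L
      next
    }
    grid <- expand.grid(a = ha, b = hb, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (nrow(grid) == 0) next
    pairs[[length(pairs) + 1L]] <- data.frame(
      gene_a = pmin(grid$a, grid$b), gene_b = pmax(grid$a, grid$b),
      organism = tab$organism[i], stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      organisms = character(0), n_source_rows = integer(0))
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  all_pairs <- do.call(rbind, pairs)
  key <- paste(all_pairs$gene_a, all_pairs$gene_b, sep = "\r")
  agg <- split(all_pairs$organism, key)
  uk <- sort(names(agg))
  parts <- strsplit(uk, "\r", fixed = TRUE)
  out <- data.frame(
    gene_a = vapply(parts, `[[`, "", 1L),
    gene_b = vapply(parts, `[[`, "", 2L),
    organisms = vapply(agg[uk], function(o) paste(sort(unique(o)),
                                                  collapse = ";"), ""),
    n_source_rows = lengths(agg[uk]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Screen synthetic-lethal pairs linking two gene sets within a scope
#'
#' A hit is an unordered pair \{x, y\} of the humanized SL pair set with one
#' endpoint in `set_a`, the other in `set_b`, and both inside `scope` (the
#' members of the disease process under study). Symmetric in
#' `set_a`/`set_b`.
#'
#' @param sl_pairs data.frame of unordered human pairs (gene_a, gene_b),
#'   e.g. a [humanize_sl()] result
#' @param set_a,set_b gene sets (e.g. members of two drug MoA models)
#' @param scope gene set both endpoints must belong to
#' @return data.frame of hits (gene_a, gene_b plus any provenance columns
#'   of `sl_pairs`)
#' @export
screen_pairs <- function(sl_pairs, set_a, set_b, scope) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(sl_pairs)))
  a <- sl_pairs$gene_a
  b <- sl_pairs$gene_b
  in_scope <- a %in% scope & b %in% scope
  linking <- (a %in% set_a & b %in% set_b) | (a %in% set_b & b %in% set_a)
  hits <- sl_pairs[in_scope & linking, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
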