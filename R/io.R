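# Readers/writers for the plain-text formats the pipeline consumes and emits:
# two-column edge lists, GMT gene-set collections, expression + clinical TSVs,
# synthetic-lethality tables and orthology maps.

#' Read an interaction network from a two-column edge-list TSV
#'
#' Lines starting with `#` are ignored; a header line is detected when the
#' first two fields are `gene_a`/`gene_b` (case-insensitive). Self-loops and
#' duplicate edges are removed so the result is a simple undirected graph.
#'
#' @param path TSV file, two tab-separated gene identifiers per line
#' @return an undirected simple `igraph` object with vertex names
#' @export
read_network <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   colClasses = "character")
  if (ncol(df) < 2) stop("edge list needs at least two columns: ", path)
  if (nrow(df) > 0 && all(tolower(unlist(df[1, 1:2])) %in% c("gene_a", "gene_b"))) {
    df <- df[-1, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(as.matrix(df[, 1:2]), directed = FALSE)
  igraph::simplify(g)
}

#' Write a network as a two-column edge-list TSV
#' @param g undirected `igraph`
#' @param path output file
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g)
  colnames(el) <- c("gene_a", "gene_b")
  write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a line are collapsed.
#'
#' @param path GMT file
#' @return named list of character vectors of gene identifiers, with the
#'   descriptions kept in `attr(, "description")`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 1L) < 3L
  if (any(bad)) stop("GMT lines need name, description and >= 1 gene: ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors
#' @param path output file
#' @param description optional vector of descriptions (recycled)
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix TSV (features x samples) plus clinical table
#'
#' @param expr_path TSV with feature identifiers in the first column and one
#'   column per sample (header = sample identifiers)
#' @param clinical_path TSV with at least `sample_id` and `pfs_months` columns
#' @return an [expression_study()] object
#' @export
read_expression_study <- function(expr_path, clinical_path) {
  expr <- read.delim(expr_path, check.names = FALSE)
  mat <- as.matrix(expr[, -1, drop = FALSE])
  rownames(mat) <- as.character(expr[[1]])
  clin <- read.delim(clinical_path, check.names = FALSE)
  expression_study(mat, clin)
}

#' Write an expression study as expression + clinical TSVs
#' @param study [expression_study()] object
#' @param expr_path,clinical_path output files
#' @export
write_expression_study <- function(study, expr_path, clinical_path) {
  df <- data.frame(feature = rownames(study$matrix), study$matrix,
                   check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$clinical, clinical_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(expr_path)
}

#' Read a synthetic-lethality interaction table
#'
#' Expects columns `gene_a`, `gene_b`, `organism`, `evidence_tag`; BioGRID
#' TAB-style headers can be accommodated via `column_map`, a named character
#' vector mapping these canonical names to the file's column names.
#'
#' @param path TSV file
#' @param column_map optional named character vector, e.g.
#'   `c(gene_a = "Official Symbol Interactor A")`
#' @return data.frame with the four canonical columns
#' @export
read_sl_table <- function(path, column_map = NULL) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  need <- c("gene_a", "gene_b", "organism", "evidence_tag")
  for (nm in need) {
    src <- if (!is.null(column_map) && nm %in% names(column_map))
      column_map[[nm]] else nm
    if (!src %in% names(df)) stop("SL table misses column: ", src)
    df[[nm]] <- df[[src]]
  }
  df[, need]
}

#' Read an orthology map
#'
#' Two-column TSV (`source_gene`, `human_gene`), optionally with an
#' `organism` column restricting each row.
#'
#' @param path TSV file
#' @return data.frame with columns `source_gene`, `human_gene` and, when
#'   present in the file, `organism`
#' @export
read_orthology <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (!all(c("source_gene", "human_gene") %in% names(df))) {
    if (ncol(df) >= 2) {
      names(df)[1:2] <- c("source_gene", "human_gene")
    } else stop("orthology map needs two columns: ", path)
  }
  keep <- intersect(c("source_gene", "human_gene", "organism"), names(df))
  df[, keep, drop = FALSE]
}

#' Write a molecular model to JSON (and optionally GraphML)
#'
#' @param model a [build_model()] result
#' @param json_path output JSON file
#' @param graphml_path optional GraphML export of the process-level graph
#' @export
write_model <- function(model, json_path, graphml_path = NULL) {
  out <- list(
    name = model$name,
    total_members = model$total_members,
    processes = lapply(model$processes, function(p) {
      list(process_id = p$process_id, seed_vertex = p$seed_vertex,
           score = p$score, members = sort(p$members))
    }),
    process_graph = model$process_graph,
    pair_table = model$pair_table
  )
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(graphml_path)) {
    pg <- process_graph_igraph(model)
    igraph::write_graph(pg, graphml_path, format = "graphml")
  }
  invisible(json_path)
}

# process-level graph as an igraph (node = process, edge = significant
# cross-process interaction load)
process_graph_igraph <- function(model) {
  ids <- vapply(model$processes, function(p) as.character(p$process_id), "")
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$size <- vapply(model$processes, function(p) length(p$members), 1L)
  pg <- model$process_graph
  if (nrow(pg) > 0) {
    g <- igraph::add_edges(g, rbind(as.character(pg$process_a),
                                    as.character(pg$process_b)))
    igraph::E(g)$edge_count <- pg$edge_count
    igraph::E(g)$adjusted_p <- pg$adjusted_p
  }
  g
}
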