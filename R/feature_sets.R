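# Provenance-tracked gene feature sets: loading from one-per-line text or
# GMT rows, identifier canonicalization through an optional id map, and
# set-union consolidation of literature- and transcriptomics-derived sets.

#' Construct a feature set
#'
#' @param name set label
#' @param features character vector of gene identifiers (deduplicated)
#' @param provenance optional named list gene -> character vector of source
#'   labels; defaults to `name` for every gene
#' @return a `feature_set` object
#' @export
feature_set <- function(name, features, provenance = NULL) {
  features <- unique(as.character(features))
  if (is.null(provenance)) {
    provenance <- setNames(rep(list(name), length(features)), features)
  }
  stopifnot(setequal(names(provenance), features))
  structure(list(name = name, features = features,
                 provenance = provenance[features]),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d features\n", x$name, length(x$features)))
  srcs <- sort(unique(unlist(x$provenance)))
  cat("  sources:", paste(srcs, collapse = ", "), "\n")
  invisible(x)
}

#' Load a feature set from a text file
#'
#' Accepts either one identifier per line or a single GMT-style row
#' (name, description, genes...). Identifiers are canonicalized (uppercased
#' by default) and optionally mapped through `id_map`; identifiers absent
#' from a supplied map are retained under their raw (canonicalized)
#' identifier and reported, never silently dropped — mapping onto the
#' network will simply miss them.
#'
#' @param path input file
#' @param name set label (for a GMT row, overrides the row's own name when
#'   given)
#' @param id_map optional named character vector: source identifier ->
#'   canonical gene identifier (keys matched after canonicalization)
#' @param canonicalize `"upper"` (default) or `"none"`
#' @return a [feature_set()]; unmapped identifiers in `attr(, "unmapped")`
#' @export
load_feature_set <- function(path, name = NULL, id_map = NULL,
                             canonicalize = c("upper", "none")) {
  canonicalize <- match.arg(canonicalize)
  if (!file.exists(path)) stop("cannot read feature set file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) >= 1 && grepl("\t", lines[1], fixed = TRUE)) {
    fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) stop("malformed GMT row in ", path)
    genes <- fields[-(1:2)]
    if (is.null(name)) name <- fields[1]
  } else {
    genes <- trimws(lines)
    if (is.null(name)) name <- basename(path)
  }
  canon <- function(x) if (canonicalize == "upper") toupper(x) else x
  genes <- unique(canon(genes))
  unmapped <- character(0)
  if (!is.null(id_map)) {
    names(id_map) <- canon(names(id_map))
    hit <- genes %in% names(id_map)
    unmapped <- genes[!hit]
    genes[hit] <- canon(unname(id_map[genes[hit]]))
    genes <- unique(genes)
    if (length(unmapped) > 0) {
      message(sprintf("%s: %d identifier(s) not in id map, kept as-is",
                      name, length(unmapped)))
    }
  }
  if (length(genes) == 0) {
    warning("feature set '", name, "' is empty after mapping")
  }
  fs <- feature_set(name, genes)
  attr(fs, "unmapped") <- unmapped
  fs
}

#' Consolidate feature sets into one provenance-tracked union
#'
#' Pure set union: commutative, associative and idempotent over its inputs.
#' Every source label attached to a gene in an input survives to the output.
#'
#' @param sets list of [feature_set()] objects (>= 1)
#' @param name label for the consolidated set
#' @return a [feature_set()]; per-source sizes and the pairwise overlap
#'   matrix are attached as `attr(, "report")`
#' @export
consolidate <- function(sets, name = "consolidated") {
  stopifnot(length(sets) >= 1,
            all(vapply(sets, inherits, TRUE, "feature_set")))
  features <- unique(unlist(lapply(sets, `[[`, "features")))
  provenance <- setNames(vector("list", length(features)), features)
  for (s in sets) {
    for (g in s$features) {
      provenance[[g]] <- sort(unique(c(provenance[[g]], s$provenance[[g]])))
    }
  }
  src_sizes <- setNames(vapply(sets, function(s) length(s$features), 1L),
                        vapply(sets, `[[`, "", "name"))
  k <- length(sets)
  overlap <- matrix(0L, k, k, dimnames = list(names(src_sizes),
                                              names(src_sizes)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    overlap[i, j] <- length(intersect(sets[[i]]$features,
                                      sets[[j]]$features))
  }
  fs <- feature_set(name, features, provenance)
  attr(fs, "report") <- list(source_sizes = src_sizes, overlap = overlap,
                             union_size = length(features))
  fs
}

#' Write a feature set as a two-column TSV (gene, sources)
#' @param fs a [feature_set()]
#' @param path output file
#' @export
write_feature_set <- function(fs, path) {
  df <- data.frame(
    gene = fs$features,
    sources = vapply(fs$provenance, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
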