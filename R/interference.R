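# Drug-disease model interference: membership overlap between a drug
# mechanism-of-action model and a disease model (or single molecular
# process), with a chi-square test of independence over a gene universe.

#' Interference between two gene sets over a universe
#'
#' Builds the 2x2 contingency (in/out drug set x in/out disease set over
#' the universe) and applies a chi-square test of independence without
#' continuity correction. A one-sided exact hypergeometric tail
#' (`exact_p`) is always reported alongside; when any expected cell is
#' below 5 a warning points at it (the chi-square approximation is kept,
#' never silently switched). Degenerate tables (an empty margin) are
#' flagged with `p_value = NA`.
#'
#' @param drug_members,disease_members gene sets (subsets of `universe`)
#' @param universe sampling frame, by default the nodes of the interaction
#'   network the models were built on
#' @param drug_name,disease_name labels carried into the result
#' @return an `interference_result` list: overlap genes/count, chi2
#'   statistic, p-values, expected counts, universe size, degeneracy flag
#' @export
interference <- function(drug_members, disease_members, universe,
                         drug_name = "drug", disease_name = "disease") {
  if (length(universe) == 0) stop("universe must be non-empty")
  universe <- unique(universe)
  if (!all(drug_members %in% universe) ||
      !all(disease_members %in% universe)) {
    stop("drug and disease sets must be subsets of the universe")
  }
  drug_members <- unique(drug_members)
  disease_members <- unique(disease_members)
  overlap <- intersect(drug_members, disease_members)
  a <- length(overlap)
  b <- length(drug_members) - a
  c_ <- length(disease_members) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2,
                dimnames = list(drug = c("in", "out"),
                                disease = c("in", "out")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  chi2 <- p <- NA_real_
  expected <- matrix(NA_real_, 2, 2)
  if (!degenerate) {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic)
    p <- ct$p.value
    expected <- ct$expected
    if (any(expected < 5)) {
      warning("expected cell count below 5; exact_p reported alongside")
    }
  }
  # one-sided over-representation tail: P(overlap >= a) drawing
  # |drug| genes from the universe with |disease| marked
  exact_p <- phyper(a - 1, length(disease_members),
                    length(universe) - length(disease_members),
                    length(drug_members), lower.tail = FALSE)
  structure(list(drug_model = drug_name, disease_unit = disease_name,
                 overlap_genes = sort(overlap), overlap_count = a,
                 chi2_statistic = chi2, p_value = p, exact_p = exact_p,
                 expected = expected, universe_size = length(universe),
                 degenerate = degenerate),
            class = "interference_result")
}

#' @export
print.interference_result <- function(x, ...) {
  cat(sprintf("<interference> %s vs %s: overlap %d (universe %d), chi2 %.3g, p %.3g, exact p %.3g%s\n",
              x$drug_model, x$disease_unit, x$overlap_count,
              x$universe_size, x$chi2_statistic, x$p_value, x$exact_p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Per-process interference profile of a drug model against a disease model
#'
#' One row per (drug process, disease process) pair plus, per disease
#' process, an aggregate row for the whole drug model — the overlap counts
#' are the quantity that color-codes drug MoA process maps against a
#' disease process.
#'
#' @param drug_model,disease_model `molecular_model` objects on a shared
#'   identifier namespace
#' @param universe gene universe for the tests
#' @return data.frame: drug_unit, disease_unit, overlap, chi2, p_value,
#'   exact_p, genes (semicolon-joined)
#' @export
interference_profile <- function(drug_model, disease_model, universe) {
  rows <- list()
  add <- function(du, dn, dgenes, pgenes) {
    r <- suppressWarnings(
      interference(dgenes, pgenes, universe, du, dn))
    rows[[length(rows) + 1L]] <<- data.frame(
      drug_unit = du, disease_unit = dn, overlap = r$overlap_count,
      chi2 = r$chi2_statistic, p_value = r$p_value, exact_p = r$exact_p,
      genes = paste(r$overlap_genes, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  dm_all <- intersect(model_members(drug_model), universe)
  for (pp in disease_model$processes) {
    dn <- sprintf("%s:process_%d", disease_model$name, pp$process_id)
    pgenes <- intersect(pp$members, universe)
    for (dp in drug_model$processes) {
      add(sprintf("%s:process_%d", drug_model$name, dp$process_id), dn,
          intersect(dp$members, universe), pgenes)
    }
    add(sprintf("%s:model", drug_model$name), dn, dm_all, pgenes)
  }
  do.call(rbind, rows)
}

#' Joint ("either/or") coverage of a disease unit by several drug models
#'
#' @param drug_member_sets list of gene sets (one per drug model)
#' @param disease_members gene set of the disease unit
#' @return list with `covered` (genes of the disease unit in at least one
#'   drug set) and `count`
#' @export
joint_coverage <- function(drug_member_sets, disease_members) {
  covered <- intersect(disease_members,
                       unique(unlist(drug_member_sets)))
  list(covered = sort(covered), count = length(covered))
}
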