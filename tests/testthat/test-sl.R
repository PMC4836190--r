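# Synthetic-lethality humanization (tag/organism filters, orthology
# expansion) and pair screening.

sl_row <- function(a, b, org = "Homo sapiens",
                   tag = "Synthetic Lethality") {
  data.frame(gene_a = a, gene_b = b, organism = org, evidence_tag = tag,
             stringsAsFactors = FALSE)
}

test_that("humanization filters, expands orthologs and deduplicates", {
  expect_equal(nrow(humanize_sl(sl_row("A", "B"))), 1)
  expect_equal(humanize_sl(sl_row("B", "A"))$gene_a, "A")   # unordered

  # excluded evidence tag
  expect_equal(nrow(humanize_sl(sl_row("A", "B", tag = "Positive Genetic"))),
               0)
  # excluded organism
  expect_equal(nrow(humanize_sl(sl_row("A", "B", org = "Danio rerio"))), 0)

  # yeast row whose genes map to {A} and {B, C}: cartesian expansion
  orth <- data.frame(organism = "Saccharomyces cerevisiae",
                     source_gene = c("YA", "YB", "YB"),
                     human_gene = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
  out <- humanize_sl(sl_row("YA", "YB", org = "Saccharomyces cerevisiae",
                            tag = "Negative Genetic"), orth)
  expect_equal(nrow(out), 2)
  expect_setequal(paste(out$gene_a, out$gene_b), c("A B", "A C"))

  # unmappable non-human rows are dropped and counted
  dropped <- humanize_sl(sl_row("YX", "YY", org = "Mus musculus"), orth)
  expect_equal(nrow(dropped), 0)
  expect_equal(attr(dropped, "n_dropped"), 1L)

  # self-pairs vanish after mapping
  orth2 <- data.frame(source_gene = c("M1", "M2"), human_gene = c("A", "A"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(humanize_sl(sl_row("M1", "M2", org = "Mus musculus"),
                                orth2)), 0)

  # idempotent on already-human tables; duplicate rows collapse
  tab <- rbind(sl_row("A", "B"), sl_row("B", "A", tag = "Negative Genetic"))
  once <- humanize_sl(tab)
  expect_equal(nrow(once), 1)
  expect_equal(once$n_source_rows, 2L)
  again <- humanize_sl(cbind(once[, c("gene_a", "gene_b")],
                             organism = "Homo sapiens",
                             evidence_tag = "Synthetic Lethality"))
  expect_equal(again[, c("gene_a", "gene_b")],
               once[, c("gene_a", "gene_b")])
})

test_that("pair screening is symmetric, scoped and monotone", {
  pairs <- humanize_sl(rbind(sl_row("PRKCH", "CCND1"),
                             sl_row("PRKCH", "PRKCI"),
                             sl_row("PRKCH", "OUTSIDE"),
                             sl_row("CCND1", "PRKCI")))
  scope <- c("PRKCH", "CCND1", "PRKCI", "MTOR", "VEGFA")
  sirolimus_like <- c("PRKCH", "MTOR")
  paclitaxel_like <- c("CCND1", "PRKCI")

  hits <- screen_pairs(pairs, sirolimus_like, paclitaxel_like, scope)
  expect_equal(nrow(hits), 2)
  expect_setequal(paste(hits$gene_a, hits$gene_b),
                  c("CCND1 PRKCH", "PRKCH PRKCI"))

  # symmetric in the two drug sets
  rev <- screen_pairs(pairs, paclitaxel_like, sirolimus_like, scope)
  expect_equal(hits[order(hits$gene_a), c("gene_a", "gene_b")],
               rev[order(rev$gene_a), c("gene_a", "gene_b")])

  # empty SL set yields no hits
  expect_equal(nrow(screen_pairs(pairs[0, ], sirolimus_like,
                                 paclitaxel_like, scope)), 0)

  # set_a == set_b: internal SL pairs of the set within scope
  internal <- screen_pairs(pairs, paclitaxel_like, paclitaxel_like, scope)
  expect_equal(paste(internal$gene_a, internal$gene_b), "CCND1 PRKCI")

  # monotone in scope and in the pair set
  smaller <- screen_pairs(pairs, sirolimus_like, paclitaxel_like,
                          c("PRKCH", "CCND1"))
  expect_lte(nrow(smaller), nrow(hits))
  more <- rbind(pairs,
                data.frame(gene_a = "MTOR", gene_b = "PRKCI",
                           organisms = "Homo sapiens", n_source_rows = 1L))
  expect_gte(nrow(screen_pairs(more, sirolimus_like, paclitaxel_like,
                               scope)), nrow(hits))
})
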