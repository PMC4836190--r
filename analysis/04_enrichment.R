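#!/usr/bin/env Rscript
# Pathway over-representation analysis of the leading disease process:
# one-sided Fisher/hypergeometric tests against the pathway collection
# with Benjamini-Hochberg adjustment.

suppressMessages(library(netresist))

ws <- "results/workspace"
net <- read_network(file.path(ws, "network.tsv"))
disease <- derive_model(
  consolidate(lapply(c("LIT-DISEASE", "TX-META", "TX-ATLAS"), function(nm) {
    load_feature_set(file.path(ws, paste0(nm, ".txt")), name = nm)
  }), name = "disease"), net, name = "disease")

sel <- disease$processes[[1]]
collection <- pathway_collection(read_gmt(file.path(ws, "pathways.gmt")))
query <- intersect(sel$members, collection$background)
cat(sprintf("Query: %d of %d process-1 members inside the pathway background (%d genes)\n\n",
            length(query), length(sel$members),
            length(collection$background)))

res <- enrich(query, collection)
cat("Enrichment table (estimate = percent of query list):\n")
print(res, row.names = FALSE)

sig <- res[!is.na(res$p_adjusted) & res$p_adjusted < 0.05, ]
cat(sprintf("\n%d pathway(s) significant at adjusted p < 0.05: %s\n",
            nrow(sig), paste(sig$pathway_id, collapse = ", ")))

dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)
write.table(res, "results/enrichment/process1_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
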