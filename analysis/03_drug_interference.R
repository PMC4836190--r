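#!/usr/bin/env Rscript
# Derive drug mechanism-of-action molecular models by the same procedure
# as the disease model and quantify their interference with the disease
# model's leading process.

suppressMessages(library(netresist))

ws <- "results/workspace"
net <- read_network(file.path(ws, "network.tsv"))
universe <- igraph::V(net)$name

disease <- derive_model(
  consolidate(lapply(c("LIT-DISEASE", "TX-META", "TX-ATLAS"), function(nm) {
    load_feature_set(file.path(ws, paste0(nm, ".txt")), name = nm)
  }), name = "disease"), net, name = "disease")

drugs <- lapply(c("drug_alpha", "drug_beta", "drug_gamma"), function(nm) {
  derive_model(load_feature_set(file.path(ws, paste0(nm, ".txt")),
                                name = nm), net, name = nm)
})
names(drugs) <- c("drug_alpha", "drug_beta", "drug_gamma")

sel <- disease$processes[[1]]
cat(sprintf("Disease process %d: %d members\n\n", sel$process_id,
            length(sel$members)))

for (nm in names(drugs)) {
  r <- suppressWarnings(
    interference(model_members(drugs[[nm]]), sel$members, universe,
                 drug_name = nm, disease_name = "process_1"))
  cat(sprintf("%s: model %d genes, overlap with process 1 = %d, chi2 p = %.3g, exact p = %.3g\n",
              nm, drugs[[nm]]$total_members, r$overlap_count,
              r$p_value, r$exact_p))
}

cov <- joint_coverage(lapply(drugs[c("drug_alpha", "drug_beta")],
                             model_members), sel$members)
cat(sprintf("\nEither/or coverage of process 1 by drug_alpha and drug_beta: %d of %d members\n",
            cov$count, length(sel$members)))

dir.create("results/interference", showWarnings = FALSE, recursive = TRUE)
prof <- do.call(rbind, lapply(drugs, interference_profile,
                              disease_model = disease,
                              universe = universe))
write.table(prof, "results/interference/profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Full per-process interference table written to results/interference/profile.tsv\n")
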