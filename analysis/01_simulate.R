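#!/usr/bin/env Rscript
# Build the synthetic study workspace: an interaction network with three
# planted dense modules, overlapping disease/drug gene sets, a pathway
# collection, train/test expression cohorts tied to progression-free
# survival, and a synthetic-lethality table with orthology map.
#
# All downstream analysis scripts read from results/workspace/.

suppressMessages(library(netresist))

seed <- 1L
ws <- simulate_workspace("results/workspace", seed = seed)

cat("Workspace written to results/workspace (seed", seed, ")\n\n")
cat("Planted modules:\n")
for (nm in names(ws$truth$membership)) {
  cat(sprintf("  %s: %d genes\n", nm, length(ws$truth$membership[[nm]])))
}
cat(sprintf("Planted expression signal: %d genes from module 1\n",
            length(ws$truth$signal_features)))
cat(sprintf("Planted SL pairs: %d (coupling drug_gamma to drug_beta)\n",
            nrow(ws$truth$planted_sl)))

net <- read_network("results/workspace/network.tsv")
cat(sprintf("\nNetwork: %d nodes, %d edges\n",
            igraph::vcount(net), igraph::ecount(net)))
jsonlite::write_json(ws$truth, "results/workspace/truth.json",
                     auto_unbox = TRUE, digits = NA)
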