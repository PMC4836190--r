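#!/usr/bin/env Rscript
# Relapse-prognosis transcript panel: dichotomize the training cohort by
# PFS (<12 months resistant, >22 sensitive), run bootstrapped LASSO over
# the disease-model genes, compute optimism-adjusted AUCs on both cohorts,
# rank processes by summed selection frequency, and screen the top
# pathway's members for PFS correlation.

suppressMessages(library(netresist))

ws <- "results/workspace"
seed <- 1L
net <- read_network(file.path(ws, "network.tsv"))
disease <- derive_model(
  consolidate(lapply(c("LIT-DISEASE", "TX-META", "TX-ATLAS"), function(nm) {
    load_feature_set(file.path(ws, paste0(nm, ".txt")), name = nm)
  }), name = "disease"), net, name = "disease")
candidates <- model_members(disease)

train <- dichotomize(read_expression_study(
  file.path(ws, "expr_train.tsv"), file.path(ws, "clinical_train.tsv")))
test <- dichotomize(read_expression_study(
  file.path(ws, "expr_test.tsv"), file.path(ws, "clinical_test.tsv")))
cat("Training cohort:\n"); print(train$class_counts)
cat("Test cohort:\n"); print(test$class_counts)

cat(sprintf("\nBootstrapped LASSO over %d candidate genes (200 runs) ...\n",
            length(candidates)))
pr <- bootstrap_lasso(train, candidates, n_boot = 200, seed = seed)
cat(sprintf("Panel: %d transcripts (lambda = %.4g)\n", length(pr$panel),
            pr$lambda))
top <- sort(pr$selection_frequency, decreasing = TRUE)[1:10]
cat("Top selection frequencies:\n")
print(round(top, 2))

auc_tr <- optimism_adjusted_auc(train, pr$panel, n_boot = 200, seed = seed)
auc_te <- optimism_adjusted_auc(test,
                                intersect(pr$panel, rownames(test$matrix)),
                                n_boot = 200, seed = seed)
cat(sprintf("\nTraining: AUC_obs %.3f, AUC_boot %.3f, AUC_test %.3f -> AUC_adj %.3f\n",
            auc_tr$auc_obs, auc_tr$auc_boot, auc_tr$auc_test,
            auc_tr$auc_adj))
cat(sprintf("Test:     AUC_obs %.3f, AUC_boot %.3f, AUC_test %.3f -> AUC_adj %.3f\n",
            auc_te$auc_obs, auc_te$auc_boot, auc_te$auc_test,
            auc_te$auc_adj))

rel <- process_relevance(pr, disease)
cat("\nProcess relevance (sum of member selection frequencies):\n")
print(rel, row.names = FALSE)

collection <- pathway_collection(read_gmt(file.path(ws, "pathways.gmt")))
enr <- enrich(intersect(disease$processes[[1]]$members,
                        collection$background), collection)
top_pw <- enr$pathway_id[1]
scr <- pfs_correlation_screen(test, collection$pathways[[top_pw]])
cat(sprintf("\nPFS correlation screen of %s members (test cohort): %d of %d at |r| >= 0.4\n",
            top_pw, sum(scr$flagged, na.rm = TRUE), nrow(scr)))
print(head(scr, 5), row.names = FALSE)

dir.create("results/panel", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(feature = names(pr$selection_frequency),
                       frequency = pr$selection_frequency,
                       in_panel = names(pr$selection_frequency) %in% pr$panel),
            "results/panel/selection_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rel, "results/panel/process_relevance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(scr, "results/panel/pfs_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(train = auc_tr, test = auc_te, panel = pr$panel),
                     "results/panel/auc.json", auto_unbox = TRUE,
                     digits = NA)
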