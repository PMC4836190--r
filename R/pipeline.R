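# End-to-end orchestration: consolidate feature sets -> derive disease and
# drug molecular models -> interference -> pathway enrichment -> transcript
# panel (train) -> panel evaluation (test) -> PFS correlation screen ->
# synthetic-lethality screen, driven by a single YAML configuration, with
# a manifest recording inputs, parameters, seeds and per-stage outputs.

default_params <- function() {
  list(
    mcode = list(vwp = 0.2, haircut = TRUE, fluff = FALSE,
                 fluff_threshold = 0.2, min_size = 3L),
    dichotomize = list(resistant_below = 12, sensitive_above = 22),
    classifier = list(n_boot = 200L),
    enrichment = list(min_overlap = 2L),
    process_edge_alpha = 0.05,
    correlation_threshold = 0.4,
    interference_alpha = 0.05,
    sl = list(tags = SL_TAGS, organisms = ORGANISMS),
    selected_process = 1L
  )
}

merge_params <- function(user, defaults = default_params()) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_params(user[[nm]], defaults[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param config a YAML file path or an equivalent nested list with `seed`,
#'   `outdir`, `inputs` (paths) and optional `params` overriding
#'   the defaults (12/22-month dichotomization, 0.4 correlation threshold,
#'   0.05 adjusted-p thresholds, 200 bootstraps, MCODE vwp 0.2 / min size 3)
#' @return validated config list with defaults filled in
#' @export
load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs),
            !is.null(config$outdir))
  if (is.null(config$seed)) stop("config must set a seed")
  config$params <- merge_params(config$params %||% list())
  flat <- function(x) if (is.list(x)) unlist(lapply(x, flat)) else x
  paths <- flat(config$inputs)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  config
}

read_gene_list <- function(path) {
  unique(toupper(trimws(readLines(path, warn = FALSE))))
}

#' Run the full analysis pipeline
#'
#' Executes consolidation, disease- and drug-model derivation,
#' interference, enrichment of the selected disease process, transcript
#' panel derivation on the training study, panel evaluation on the test
#' study (skipped with a log entry when absent), the PFS correlation
#' screen, and the synthetic-lethality screen. Any stage failure aborts
#' with a stage-named error; outputs of completed stages are retained.
#'
#' @param config path to a YAML config or a config list
#'   (see [load_pipeline_config()])
#' @return the run manifest (invisibly also written to
#'   `outdir/manifest.json`): input checksums, parameters, seed, per-stage
#'   output paths
#' @export
run_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pars <- config$params
  log <- character(0)
  stages <- list()
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out_path <- function(...) file.path(outdir, paste0(...))

  net <- stage("load_inputs", function() read_network(config$inputs$network))

  disease_fs <- stage("consolidate", function() {
    sets <- lapply(names(config$inputs$disease_sets), function(nm) {
      load_feature_set(config$inputs$disease_sets[[nm]], name = nm)
    })
    fs <- consolidate(sets, name = "disease")
    write_feature_set(fs, out_path("disease_features.tsv"))
    stages$consolidate <<- out_path("disease_features.tsv")
    note("consolidate: %d unique features from %d sets",
         length(fs$features), length(sets))
    fs
  })

  mcode <- do.call(mcode_params, pars$mcode)
  disease_model <- stage("disease_model", function() {
    m <- derive_model(disease_fs, net, params = mcode, name = "disease",
                      alpha = pars$process_edge_alpha)
    write_model(m, out_path("disease_model.json"),
                out_path("disease_model.graphml"))
    stages$disease_model <<- out_path("disease_model.json")
    note("disease model: %d processes, %d members",
         length(m$processes), m$total_members)
    m
  })

  drug_models <- stage("drug_models", function() {
    ms <- lapply(names(config$inputs$drug_sets), function(nm) {
      fs <- load_feature_set(config$inputs$drug_sets[[nm]], name = nm)
      m <- derive_model(fs, net, params = mcode, name = nm,
                        alpha = pars$process_edge_alpha)
      write_model(m, out_path(nm, "_model.json"))
      m
    })
    names(ms) <- names(config$inputs$drug_sets)
    stages$drug_models <<- out_path(names(ms), "_model.json")
    note("drug models: %s",
         paste(sprintf("%s=%d members", names(ms),
                       vapply(ms, `[[`, 1L, "total_members")),
               collapse = ", "))
    ms
  })

  universe <- igraph::V(net)$name
  sel_id <- pars$selected_process
  sel_process <- stage("interference", function() {
    sel <- Filter(function(p) p$process_id == sel_id,
                  disease_model$processes)
    if (length(sel) == 0) stop("selected process ", sel_id, " not in model")
    sel <- sel[[1]]
    prof <- do.call(rbind, lapply(drug_models, function(dm) {
      interference_profile(dm, disease_model, universe)
    }))
    write.table(prof, out_path("interference.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cov <- joint_coverage(lapply(drug_models, model_members), sel$members)
    jsonlite::write_json(
      list(selected_process = sel_id,
           process_size = length(sel$members),
           joint_coverage = cov$count, covered_genes = cov$covered),
      out_path("joint_coverage.json"), auto_unbox = TRUE, digits = NA)
    stages$interference <<- c(out_path("interference.tsv"),
                              out_path("joint_coverage.json"))
    note("interference: selected process %d (%d members), joint coverage %d",
         sel_id, length(sel$members), cov$count)
    sel
  })

  enr <- stage("enrichment", function() {
    collection <- pathway_collection(read_gmt(config$inputs$pathways))
    query <- intersect(sel_process$members, collection$background)
    e <- enrich(query, collection,
                min_overlap = pars$enrichment$min_overlap)
    write.table(e, out_path("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    stages$enrichment <<- out_path("enrichment.tsv")
    note("enrichment: %d pathways tested, top %s", sum(!is.na(e$p_raw)),
         e$pathway_id[1])
    e
  })

  train <- read_expression_study(config$inputs$expression_train$expression,
                                 config$inputs$expression_train$clinical)
  train <- dichotomize(train, pars$dichotomize$resistant_below,
                       pars$dichotomize$sensitive_above)

  panel_res <- stage("panel", function() {
    set.seed(config$seed)
    pr <- bootstrap_lasso(train, model_members(disease_model),
                          n_boot = pars$classifier$n_boot,
                          seed = config$seed)
    pr$auc <- optimism_adjusted_auc(train, pr$panel,
                                    n_boot = pars$classifier$n_boot,
                                    seed = config$seed)
    panel_df <- data.frame(feature = names(pr$selection_frequency),
                           coefficient = 0, selected = FALSE,
                           frequency = pr$selection_frequency)
    panel_df$coefficient[match(pr$panel, panel_df$feature)] <-
      pr$coefficients
    panel_df$selected[match(pr$panel, panel_df$feature)] <- TRUE
    panel_df <- panel_df[order(-panel_df$frequency, panel_df$feature), ]
    write.table(panel_df, out_path("panel.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    rel <- process_relevance(pr, disease_model)
    write.table(rel, out_path("process_relevance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(c(pr$auc[c("auc_obs", "auc_boot", "auc_test",
                                    "auc_adj")],
                           list(panel = pr$panel, lambda = pr$lambda)),
                         out_path("panel_auc_train.json"),
                         auto_unbox = TRUE, digits = NA)
    stages$panel <<- c(out_path("panel.tsv"),
                       out_path("process_relevance.tsv"),
                       out_path("panel_auc_train.json"))
    note("panel: %d features, training AUC_adj %.3f",
         length(pr$panel), pr$auc$auc_adj)
    pr
  })

  test_study <- NULL
  if (!is.null(config$inputs$expression_test)) {
    stage("panel_evaluation", function() {
      ts <- read_expression_study(config$inputs$expression_test$expression,
                                  config$inputs$expression_test$clinical)
      ts <- dichotomize(ts, pars$dichotomize$resistant_below,
                        pars$dichotomize$sensitive_above)
      test_study <<- ts
      panel_in_test <- intersect(panel_res$panel, rownames(ts$matrix))
      auc <- optimism_adjusted_auc(ts, panel_in_test,
                                   n_boot = pars$classifier$n_boot,
                                   seed = config$seed)
      jsonlite::write_json(auc[c("auc_obs", "auc_boot", "auc_test",
                                 "auc_adj")],
                           out_path("panel_auc_test.json"),
                           auto_unbox = TRUE, digits = NA)
      stages$panel_evaluation <<- out_path("panel_auc_test.json")
      note("panel evaluation: test AUC_adj %.3f", auc$auc_adj)
    })
  } else {
    note("panel evaluation: no test study configured, stage skipped")
  }

  stage("correlation_screen", function() {
    study <- test_study %||% train
    top_pw <- enr$pathway_id[1]
    collection <- pathway_collection(read_gmt(config$inputs$pathways))
    feats <- intersect(collection$pathways[[top_pw]],
                       rownames(study$matrix))
    scr <- pfs_correlation_screen(study, feats,
                                  threshold = pars$correlation_threshold)
    write.table(scr, out_path("pfs_correlation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stages$correlation_screen <<- out_path("pfs_correlation.tsv")
    note("correlation screen: %d of %d features flagged at |r| >= %.2f",
         sum(scr$flagged, na.rm = TRUE), nrow(scr),
         pars$correlation_threshold)
  })

  stage("sl_screen", function() {
    sl <- read_sl_table(config$inputs$sl_table)
    orth <- if (!is.null(config$inputs$orthology))
      read_orthology(config$inputs$orthology) else NULL
    pairs <- humanize_sl(sl, orth, allowed_tags = pars$sl$tags,
                         allowed_organisms = pars$sl$organisms)
    nm <- names(drug_models)
    a <- pars$sl$set_a %||% nm[1]
    b <- pars$sl$set_b %||% nm[min(2, length(nm))]
    hits <- screen_pairs(pairs, model_members(drug_models[[a]]),
                         model_members(drug_models[[b]]),
                         scope = sel_process$members)
    write.table(hits, out_path("sl_hits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    stages$sl_screen <<- out_path("sl_hits.tsv")
    note("SL screen (%s vs %s within process %d): %d hit(s)",
         a, b, sel_id, nrow(hits))
  })

  flat <- function(x) if (is.list(x)) unlist(lapply(x, flat)) else x
  input_paths <- flat(config$inputs)
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    inputs = as.list(tools::md5sum(input_paths)),
    params = pars,
    stages = stages,
    log = log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
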