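# Relapse prognosis machinery: PFS dichotomization, bootstrapped LASSO
# transcript-panel derivation with selection frequencies, optimism-adjusted
# AUC of the panel logistic model, process-level relevance scores, the
# Pearson PFS-correlation screen, and blood-detectability annotation.

#' Construct an expression study
#'
#' @param matrix numeric feature x sample matrix (normalized, log-scale
#'   assumed), with feature row names and sample column names
#' @param clinical data.frame with `sample_id` and `pfs_months` columns,
#'   one row per sample, same order/ids as the matrix columns
#' @param labels optional character vector in
#'   `c("resistant", "sensitive", "excluded")`
#' @return an `expression_study`
#' @export
expression_study <- function(matrix, clinical, labels = NULL) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)),
            all(c("sample_id", "pfs_months") %in% names(clinical)))
  clinical$sample_id <- as.character(clinical$sample_id)
  if (!identical(colnames(matrix), clinical$sample_id)) {
    if (!setequal(colnames(matrix), clinical$sample_id)) {
      stop("matrix columns and clinical sample_ids disagree")
    }
    clinical <- clinical[match(colnames(matrix), clinical$sample_id), ,
                         drop = FALSE]
    rownames(clinical) <- NULL
  }
  if (!is.null(labels)) stopifnot(length(labels) == ncol(matrix))
  structure(list(matrix = matrix, clinical = clinical, labels = labels),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %d features x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Dichotomize a study by progression-free survival
#'
#' PFS strictly below `resistant_below` months labels a sample resistant;
#' strictly above `sensitive_above` months labels it sensitive; everything
#' in between (both boundaries included) is excluded from classification.
#'
#' @param study an [expression_study()]
#' @param resistant_below months (default 12)
#' @param sensitive_above months (default 22)
#' @return the study with `labels` set and class counts in `class_counts`
#' @export
dichotomize <- function(study, resistant_below = 12, sensitive_above = 22) {
  stopifnot(inherits(study, "expression_study"),
            resistant_below <= sensitive_above)
  pfs <- study$clinical$pfs_months
  if (any(is.na(pfs))) stop("PFS must be present for all samples")
  labels <- ifelse(pfs < resistant_below, "resistant",
                   ifelse(pfs > sensitive_above, "sensitive", "excluded"))
  study$labels <- labels
  study$class_counts <- c(resistant = sum(labels == "resistant"),
                          sensitive = sum(labels == "sensitive"),
                          excluded = sum(labels == "excluded"))
  study
}

# design matrix of labeled samples (samples x features), with y as factor
# sensitive/resistant (resistant = positive class)
labeled_design <- function(study, features) {
  if (is.null(study$labels)) stop("study must be dichotomized first")
  keep <- study$labels %in% c("resistant", "sensitive")
  feats <- intersect(features, rownames(study$matrix))
  if (length(feats) == 0) stop("no candidate features present in the study")
  x <- t(study$matrix[feats, keep, drop = FALSE])
  y <- factor(study$labels[keep], levels = c("sensitive", "resistant"))
  if (any(table(y) < 2)) {
    stop("need at least 2 samples per class after dichotomization (",
         paste(sprintf("%s=%d", levels(y), table(y)), collapse = ", "), ")")
  }
  const <- apply(x, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning(sum(const), " constant feature column(s) dropped")
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 non-constant candidate features")
  list(x = x, y = y)
}

# per-class stratified fold assignment
stratified_folds <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

# stratified bootstrap resample indices (with replacement, per class)
stratified_resample <- function(y) {
  unlist(lapply(levels(y), function(cl) {
    idx <- which(y == cl)
    sample(idx, length(idx), replace = TRUE)
  }), use.names = FALSE)
}

#' Bootstrapped LASSO transcript-panel derivation
#'
#' Fits an L1-penalized logistic model on the labeled samples restricted to
#' a candidate feature list, with the penalty chosen at the
#' cross-validated-deviance minimum (10-fold, stratified). The panel is the
#' set of nonzero-coefficient features of this single full-data fit. Per
#' bootstrap resample (with replacement, stratified by class) the same
#' CV-min-lambda fit is repeated and the per-feature selection frequency is
#' the fraction of resamples with a nonzero coefficient.
#'
#' @param study dichotomized [expression_study()]
#' @param candidates candidate feature identifiers (e.g. the member genes
#'   of a molecular model)
#' @param n_boot bootstrap runs (default 200)
#' @param seed integer seed governing folds and resamples
#' @param nfolds cross-validation folds (default 10)
#' @return a `panel_result`: `panel`, `coefficients` (log-odds scale),
#'   `selection_frequency`, `lambda`
#' @export
bootstrap_lasso <- function(study, candidates, n_boot = 200L, seed = 1L,
                            nfolds = 10L) {
  d <- labeled_design(study, candidates)
  set.seed(seed)
  foldid <- stratified_folds(d$y, nfolds)
  cvfit <- glmnet::cv.glmnet(d$x, d$y, family = "binomial",
                             type.measure = "deviance", foldid = foldid)
  lambda <- cvfit$lambda.min
  cf <- as.matrix(coef(cvfit, s = "lambda.min"))[-1, 1]
  panel <- names(cf)[cf != 0]

  sel <- setNames(numeric(ncol(d$x)), colnames(d$x))
  for (b in seq_len(n_boot)) {
    idx <- stratified_resample(d$y)
    xb <- d$x[idx, , drop = FALSE]
    yb <- d$y[idx]
    keep <- apply(xb, 2, function(v) stats::var(v) > 0)
    fid <- stratified_folds(yb, nfolds)
    cvb <- glmnet::cv.glmnet(xb[, keep, drop = FALSE], yb,
                             family = "binomial",
                             type.measure = "deviance", foldid = fid)
    cb <- as.matrix(coef(cvb, s = "lambda.min"))[-1, 1]
    nz <- names(cb)[cb != 0]
    sel[nz] <- sel[nz] + 1
  }
  structure(list(panel = panel, coefficients = cf[panel],
                 selection_frequency = sel / n_boot, lambda = lambda,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("<panel_result> %d features (lambda %.4g, %d bootstraps)\n",
              length(x$panel), x$lambda, x$n_boot))
  if (!is.null(x$auc)) {
    cat(sprintf("  AUC obs %.3f boot %.3f test %.3f adj %.3f\n",
                x$auc$auc_obs, x$auc$auc_boot, x$auc$auc_test,
                x$auc$auc_adj))
  }
  invisible(x)
}

#' Optimism-adjusted AUC of a panel logistic model
#'
#' An unpenalized logistic model on the panel features is fit and evaluated
#' on the full labeled data (`auc_obs`). Per bootstrap resample the model is
#' refit; `auc_boot` is its AUC on the resample and `auc_test` its AUC on
#' the full data; the reported values are means over runs, and
#' `auc_adj = auc_obs - (auc_boot - auc_test)`. AUC uses the rank
#' (Mann-Whitney) method with ties given 0.5 credit. One-class resamples
#' are redrawn and counted.
#'
#' @param study dichotomized [expression_study()]
#' @param panel non-empty feature identifier vector
#' @param n_boot bootstrap runs (default 200)
#' @param seed integer seed
#' @return list: `auc_obs`, `auc_boot`, `auc_test`, `auc_adj`, `n_redrawn`
#' @export
optimism_adjusted_auc <- function(study, panel, n_boot = 200L, seed = 1L) {
  if (length(panel) == 0) stop("panel must be non-empty")
  d <- labeled_design(study, panel)
  df <- data.frame(d$x, check.names = TRUE)
  pos <- d$y == "resistant"
  fit_full <- suppressWarnings(
    glm(pos ~ ., data = df, family = binomial()))
  auc_obs <- auc_rank(predict(fit_full, type = "link"), pos)

  set.seed(seed)
  n <- nrow(df)
  boot <- test <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(pos[idx])) == 2) break
      n_redrawn <- n_redrawn + 1L
    }
    fit_b <- suppressWarnings(
      glm(pos[idx] ~ ., data = df[idx, , drop = FALSE],
          family = binomial()))
    boot[b] <- auc_rank(predict(fit_b, type = "link"), pos[idx])
    test[b] <- auc_rank(predict(fit_b, newdata = df, type = "link"), pos)
  }
  auc_boot <- mean(boot)
  auc_test <- mean(test)
  list(auc_obs = auc_obs, auc_boot = auc_boot, auc_test = auc_test,
       auc_adj = auc_obs - (auc_boot - auc_test), n_redrawn = n_redrawn)
}

#' Process-level relevance of a transcript panel
#'
#' Per molecular process, the sum of bootstrap selection frequencies over
#' its member features — the quantity that color-codes the process map of
#' the disease model.
#'
#' @param panel_result a [bootstrap_lasso()] result
#' @param model a `molecular_model` on the same feature namespace
#' @return data.frame (process_id, n_members, relevance), sorted by
#'   relevance descending
#' @export
process_relevance <- function(panel_result, model) {
  freq <- panel_result$selection_frequency
  rows <- lapply(model$processes, function(p) {
    f <- freq[intersect(p$members, names(freq))]
    data.frame(process_id = p$process_id, n_members = length(p$members),
               relevance = sum(f))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$relevance, out$process_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation screen of features against PFS
#'
#' Pearson r of each feature's expression against PFS in months over all
#' samples with PFS (the screen is not restricted to the dichotomized
#' extremes). Features with |r| at or above the threshold are flagged;
#' zero-variance features get an undefined r (NA) and a note rather than
#' an error.
#'
#' @param study an [expression_study()]
#' @param features feature identifiers (default: all rows)
#' @param threshold flag threshold on |r| (default 0.4)
#' @return data.frame: feature, pearson_r, n, flagged, note
#' @export
pfs_correlation_screen <- function(study, features = NULL, threshold = 0.4) {
  stopifnot(inherits(study, "expression_study"))
  if (is.null(features)) features <- rownames(study$matrix)
  features <- intersect(features, rownames(study$matrix))
  keep <- !is.na(study$clinical$pfs_months)
  if (sum(keep) < 3) stop("need at least 3 samples with PFS")
  pfs <- study$clinical$pfs_months[keep]
  rows <- lapply(features, function(f) {
    v <- study$matrix[f, keep]
    if (stats::var(v) == 0) {
      data.frame(feature = f, pearson_r = NA_real_, n = length(v),
                 flagged = FALSE, note = "zero variance",
                 stringsAsFactors = FALSE)
    } else {
      r <- cor(v, pfs, method = "pearson")
      data.frame(feature = f, pearson_r = r, n = length(v),
                 flagged = abs(r) >= threshold, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$pearson_r), out$feature, na.last = TRUE), ,
      drop = FALSE]
}

#' Blood-detectability annotation of biomarker candidates
#'
#' A gene is considered detectable in circulation when any criterion holds:
#' (i) annotated secreted/extracellular, (ii) reported measurable in blood,
#' (iii) reported as an ovarian-cancer biomarker. Criteria arrive as named
#' gene lists; a gene mentioned in no list is flagged unannotated.
#'
#' @param genes character vector
#' @param annotation_tables named list of character vectors
#'   (criterion -> genes satisfying it)
#' @return data.frame: gene, one logical column per criterion, `detectable`,
#'   `unannotated`
#' @export
annotate_blood_detectability <- function(genes, annotation_tables) {
  stopifnot(is.list(annotation_tables))
  if (length(annotation_tables) > 0) {
    stopifnot(!is.null(names(annotation_tables)))
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (crit in names(annotation_tables)) {
    out[[crit]] <- genes %in% annotation_tables[[crit]]
  }
  flags <- as.matrix(out[, -1, drop = FALSE])
  out$detectable <- if (ncol(flags) > 0) rowSums(flags) > 0 else FALSE
  out$unannotated <- if (ncol(flags) > 0) rowSums(flags) == 0 else TRUE
  out
}
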