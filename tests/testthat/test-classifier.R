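# PFS dichotomization, panel derivation, optimism-adjusted AUC, process
# relevance, correlation screen and blood-detectability annotation.

test_that("dichotomization uses strict inequalities at both boundaries", {
  st <- dichotomize(tiny_study(c(5, 12, 15, 22, 30)))
  expect_equal(st$labels, c("resistant", "excluded", "excluded",
                            "excluded", "sensitive"))
  expect_equal(unname(st$class_counts), c(1L, 1L, 3L))

  # synthetic stand-in cohorts carrying the printed clinical margins
  train <- tiny_study(synthetic_cohort_pfs(82, 63, 226 - 82 - 63, seed = 1))
  train <- dichotomize(train)
  expect_equal(unname(train$class_counts[c("resistant", "sensitive")]),
               c(82L, 63L))
  test <- dichotomize(tiny_study(synthetic_cohort_pfs(29, 45, 110 - 29 - 45,
                                                      seed = 2)))
  expect_equal(unname(test$class_counts["resistant"]), 29L)

  # a one-class cohort errors at fit time with an informative message
  allsens <- dichotomize(tiny_study(rep(50, 10)))
  expect_error(bootstrap_lasso(allsens, c("FA", "FB", "FC"), n_boot = 2),
               "per class")
})

test_that("rank AUC equals the all-pairs oracle and handles ties", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(pos)) < 2) pos[1:2] <- c(TRUE, FALSE)
    scores <- round(rnorm(n), 1)   # coarse rounding forces ties
    expect_equal(auc_rank(scores, pos), oracle_auc_allpairs(scores, pos),
                 tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(22)
    pos <- rep(c(TRUE, FALSE), each = 20)
    scores <- rnorm(40) + pos
    expect_equal(auc_rank(scores, pos),
                 as.numeric(pROC::auc(pROC::roc(pos, scores,
                                                quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("perfectly separating features are always selected", {
  set.seed(8)
  n <- 40
  sep <- c(rnorm(n / 2, 3), rnorm(n / 2, -3))   # clean separation
  mat <- rbind(SEP = sep, NOISE1 = rnorm(n), NOISE2 = rnorm(n))
  colnames(mat) <- sprintf("S%02d", 1:n)
  st <- expression_study(mat, data.frame(
    sample_id = colnames(mat),
    pfs_months = c(rep(5, n / 2), rep(30, n / 2))))
  st <- dichotomize(st)
  pr <- bootstrap_lasso(st, rownames(mat), n_boot = 25, seed = 4)
  expect_equal(unname(pr$selection_frequency["SEP"]), 1.0)
  expect_true("SEP" %in% pr$panel)
})

test_that("panel derivation is deterministic under a fixed seed", {
  st <- simulate_expression(expression_sim_spec(
    25, 25, 60, signal_features = sprintf("F%04d", 1:5),
    effect_size = 1.5, seed = 14))
  st <- dichotomize(st)
  a <- bootstrap_lasso(st, rownames(st$matrix), n_boot = 15, seed = 99)
  b <- bootstrap_lasso(st, rownames(st$matrix), n_boot = 15, seed = 99)
  expect_identical(a, b)
})

test_that("planted signal outranks noise in selection frequency", {
  sig <- sprintf("F%04d", 1:8)
  st <- dichotomize(simulate_expression(expression_sim_spec(
    40, 40, 80, signal_features = sig, effect_size = 1.5, seed = 31)))
  pr <- bootstrap_lasso(st, rownames(st$matrix), n_boot = 30, seed = 5)
  noise <- setdiff(names(pr$selection_frequency), sig)
  expect_gt(mean(pr$selection_frequency[sig]),
            mean(pr$selection_frequency[noise]))
})

test_that("optimism-adjusted AUC obeys its identity and null calibration", {
  sig <- sprintf("F%04d", 1:5)
  st <- dichotomize(simulate_expression(expression_sim_spec(
    30, 30, 40, signal_features = sig, effect_size = 1, seed = 7)))
  auc <- optimism_adjusted_auc(st, sig, n_boot = 40, seed = 2)
  expect_identical(auc$auc_adj,
                   auc$auc_obs - (auc$auc_boot - auc$auc_test))
  expect_gt(auc$auc_obs, 0.5)
  expect_gte(auc$auc_obs, auc$auc_adj)   # optimism is non-negative here

  # labels independent of features: adjusted AUC near 0.5 on average
  adj <- vapply(1:5, function(s) {
    null <- dichotomize(simulate_expression(expression_sim_spec(
      30, 30, 10, effect_size = 0, seed = 100 + s)))
    optimism_adjusted_auc(null, rownames(null$matrix)[1:4],
                          n_boot = 40, seed = s)$auc_adj
  }, 0)
  expect_gt(mean(adj), 0.35)
  expect_lt(mean(adj), 0.65)

  expect_error(optimism_adjusted_auc(st, character(0)), "non-empty")
})

test_that("process relevance sums member selection frequencies", {
  net <- igraph::disjoint_union(complete_named(4, "A"),
                                complete_named(4, "B"))
  model <- build_model(mcode_predict(net), net)
  pr <- structure(list(selection_frequency = c(
    A01 = 0.9, A02 = 0.8, A03 = 0.7, B01 = 0.1)), class = "panel_result")
  rel <- process_relevance(pr, model)
  expect_equal(rel$relevance[1], 2.4)
  expect_equal(rel$relevance[2], 0.1)

  # identical member sets score identically; empty overlap scores zero
  pr0 <- structure(list(selection_frequency = c(Z1 = 1)),
                   class = "panel_result")
  expect_equal(process_relevance(pr0, model)$relevance, c(0, 0))
})

test_that("PFS correlation screen matches closed forms and flags", {
  set.seed(61)
  n <- 300
  pfs <- rtruncnorm(n, 20, 10, 1, Inf)
  mat <- rbind(NEGPFS = -pfs,
               NOISE = rnorm(n),
               NEARPFS = pfs + rnorm(n, sd = 0.1 * sd(pfs)),
               FLAT = rep(1, n))
  colnames(mat) <- sprintf("S%03d", 1:n)
  st <- expression_study(mat, data.frame(sample_id = colnames(mat),
                                         pfs_months = pfs))
  scr <- pfs_correlation_screen(st)
  r <- setNames(scr$pearson_r, scr$feature)
  expect_equal(unname(r["NEGPFS"]), -1, tolerance = 1e-12)
  expect_lt(abs(r["NOISE"]), 0.4)
  expect_gt(r["NEARPFS"], 0.9)
  expect_true(is.na(r["FLAT"]))
  expect_equal(scr$note[scr$feature == "FLAT"], "zero variance")
  expect_true(scr$flagged[scr$feature == "NEGPFS"])
  expect_false(scr$flagged[scr$feature == "NOISE"])

  # implementation equals the textbook covariance/sd oracle
  for (i in 1:5) {
    x <- rnorm(50); y <- rnorm(50)
    st2 <- expression_study(matrix(x, 1, dimnames = list("F1", sprintf("T%02d", 1:50))),
                            data.frame(sample_id = sprintf("T%02d", 1:50),
                                       pfs_months = abs(y) + 1))
    got <- pfs_correlation_screen(st2)$pearson_r
    expect_equal(got, oracle_pearson(x, abs(y) + 1), tolerance = 1e-12)
  }
})

test_that("blood-detectability annotation combines criteria correctly", {
  tables <- list(secreted = c("VEGFA_LIKE"),
                 blood = c("VEGFA_LIKE", "ONLY_BLOOD"),
                 ovarian_biomarker = character(0))
  ann <- annotate_blood_detectability(
    c("VEGFA_LIKE", "ONLY_BLOOD", "UNKNOWN"), tables)
  expect_equal(ann$detectable, c(TRUE, TRUE, FALSE))
  expect_equal(ann$unannotated, c(FALSE, FALSE, TRUE))
  expect_equal(unlist(ann[ann$gene == "ONLY_BLOOD",
                          c("secreted", "blood", "ovarian_biomarker")],
                      use.names = FALSE), c(FALSE, TRUE, FALSE))

  none <- annotate_blood_detectability(c("A", "B"), list())
  expect_true(all(none$unannotated))
  expect_false(any(none$detectable))
})
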