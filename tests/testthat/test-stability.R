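test_that("fold plans stratify, partition, and repeat correctly", {
  y <- rep(c("complicated", "uncomplicated"), c(52, 176))
  names(y) <- sprintf("s%03d", seq_along(y))
  plans <- make_fold_plans(y, K = 5, R = 10, seed = 4)
  expect_length(plans, 50)
  for (r in 1:10) {
    these <- Filter(function(p) p$repeat_ == r, plans)
    test_ids <- unlist(lapply(these, `[[`, "test_ids"))
    expect_setequal(test_ids, names(y))        # partition per repeat
    expect_length(test_ids, length(y))
    for (p in these) {
      expect_length(intersect(p$train_ids, p$test_ids), 0)
      npos <- sum(y[p$test_ids] == "complicated")
      expect_true(npos %in% c(10, 11))         # 52/5 stratified ideal
    }
  }
  # each sample appears in exactly R test sets
  all_test <- table(unlist(lapply(plans, `[[`, "test_ids")))
  expect_true(all(all_test == 10))
  expect_identical(make_fold_plans(y, 5, 2, seed = 4)[[1]],
                   plans[[1]])
})

test_that("grid tuning is exhaustive with first-row tie-breaking", {
  b <- blob_data(n_min = 20, n_maj = 40, sep = 3, seed = 91)
  single <- tune_hyperparameters(b$X, b$y, "logit",
                                 data.frame(lambda = 0.7), seed = 1)
  expect_equal(single$params$lambda, 0.7)
  dup <- tune_hyperparameters(b$X, b$y, "logit",
                              data.frame(lambda = c(0.5, 0.5, 0.5)),
                              seed = 1)
  expect_equal(length(dup$scores), 3)
  expect_equal(dup$params$lambda, 0.5)
  expect_true(all(dup$scores == dup$scores[1])) # duplicated rows tie
})

test_that("tuning recovers an obviously superior setting", {
  # lambda large enough to drown the signal loses to a sane penalty
  wins <- 0
  for (s in 1:5) {
    b <- blob_data(n_min = 15, n_maj = 30, sep = 2.5, seed = 200 + s)
    tu <- tune_hyperparameters(b$X, b$y, "logit",
                               data.frame(lambda = c(0.5, 5e4)), seed = s)
    if (tu$params$lambda == 0.5) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

make_mini_config <- function(seed = 5, ...) {
  run_config(seed = seed, n_repeats = 2, rfe_target = 8,
             selector_params = list(rf_trees = 100L, mrmr_k = 5L),
             grids = list(brf = data.frame(n_trees = 50L, max_depth = 0L)),
             ...)
}

test_that("discovery runs end-to-end, is deterministic, and finds signal", {
  co <- small_cohort(seed = 97)
  mat <- quantile_normalize(co$expr)
  res1 <- run_discovery(mat, co$pheno, make_mini_config())
  res2 <- run_discovery(mat, co$pheno, make_mini_config())
  expect_identical(res1$cv_report$iterations, res2$cv_report$iterations)
  expect_identical(res1$stability$table, res2$stability$table)
  expect_equal(nrow(res1$cv_report$iterations), 10) # R*K
  auc <- res1$cv_report$summary
  expect_gte(auc$mean[auc$metric == "auroc"], 0.85)
  st <- res1$stability$table
  strong_scores <- st$normalized_score[st$feature %in% co$truth$strong_genes]
  expect_true(all(strong_scores >= 80))
  # tallies sum to the per-fold RFE output sizes
  expect_equal(sum(st$times_selected),
               sum(vapply(res1$fold_logs,
                          function(l) length(l$selected), numeric(1))))
})

test_that("poisoning test-fold labels leaves trained models bit-identical", {
  co <- small_cohort(seed = 101)
  mat <- quantile_normalize(co$expr)
  cfg <- make_mini_config(seed = 6)
  labels <- setNames(co$pheno$outcome, co$pheno$sample_id)
  plans <- make_fold_plans(labels, cfg$n_folds, cfg$n_repeats, cfg$seed)
  base <- run_discovery(mat, co$pheno, cfg, plans = plans)

  poisoned <- co$pheno
  test_ids <- plans[[1]]$test_ids
  flip <- poisoned$sample_id %in% test_ids
  poisoned$outcome[flip] <- ifelse(poisoned$outcome[flip] == "complicated",
                                   "uncomplicated", "complicated")
  pois <- run_discovery(mat, poisoned, cfg, plans = plans)
  l1 <- base$fold_logs[[1]]; l2 <- pois$fold_logs[[1]]
  expect_identical(l1$selected, l2$selected)
  expect_identical(l1$params, l2$params)
  expect_identical(l1$signature, l2$signature) # same trained model
  # but the reported test metrics do change
  expect_false(isTRUE(all.equal(base$cv_report$iterations$auroc[1],
                                pois$cv_report$iterations$auroc[1])))
})

test_that("a single-class training fold aborts with a diagnostic", {
  co <- small_cohort(seed = 103, n_samples = 30)
  ph <- co$pheno
  ph$outcome <- c("complicated", rep("uncomplicated", 29))
  labels <- setNames(ph$outcome, ph$sample_id)
  plans <- make_fold_plans(labels, 5, 1, seed = 1)
  expect_error(
    suppressWarnings(run_discovery(co$expr, ph, make_mini_config(),
                                   plans = plans)),
    "single class")
})

test_that("stability scores normalize counts and threshold the shortlist", {
  rep <- summarize_stability(c(RETN = 50, OLAH = 42, X1 = 0, X2 = 29),
                             R = 10, K = 5)
  tab <- rep$table
  expect_equal(tab$normalized_score[tab$feature == "RETN"], 100)
  expect_equal(tab$normalized_score[tab$feature == "OLAH"], 84)
  expect_setequal(rep$shortlist, c("RETN", "OLAH"))
  expect_false("X1" %in% rep$shortlist)
  expect_error(summarize_stability(c(a = 51), R = 10, K = 5), "0..R\\*K")
})

test_that("reports serialize to the documented TSV shapes", {
  co <- small_cohort(seed = 107)
  res <- run_discovery(co$expr, co$pheno, make_mini_config(seed = 2))
  dir <- withr::local_tempdir()
  write_discovery_reports(res, dir)
  perf <- read.delim(file.path(dir, "cv_metrics.tsv"), check.names = FALSE)
  expect_identical(names(perf), c("sampler-classifier", "Sensitivity (CI)",
                                  "Specificity (CI)", "AUROC (CI)",
                                  "MCC (CI)"))
  stab <- read.delim(file.path(dir, "stability.tsv"))
  expect_identical(names(stab), c("feature", "times_selected",
                                  "normalized_score"))
})

test_that("mean AUROC never decreases in the planted effect size", {
  # shared-seed cohorts differing only in a fixed additive effect delta
  base <- generate_cohort(synthetic_spec(n_samples = 60, n_genes = 120,
                                         n_strong = 0, n_weak = 0,
                                         severity_effect = 0, seed = 55))
  pos <- base$pheno$outcome == "complicated"
  target_genes <- rownames(base$expr)[11:15]
  cfg <- run_config(seed = 8, n_repeats = 1, rfe_target = 6,
                    classifier = "logit",
                    selector_params = list(rf_trees = 60L, mrmr_k = 4L),
                    grids = list(logit = data.frame(lambda = 1)))
  aucs <- vapply(c(0, 0.5, 1, 2), function(delta) {
    expr <- unclass(base$expr)
    expr[target_genes, pos] <- expr[target_genes, pos] + delta
    mat <- expression_matrix(expr, rownames(base$expr),
                             colnames(base$expr))
    res <- run_discovery(mat, base$pheno, cfg)
    res$cv_report$summary$mean[res$cv_report$summary$metric == "auroc"]
  }, numeric(1))
  expect_true(all(diff(aucs) >= -1e-9))
  expect_lt(aucs[1], 0.75) # no signal, no severity: near chance
  expect_gt(aucs[4], 0.9)
})
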