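# stratified fold assignment: within each class, shuffle and deal
# round-robin, so per-fold class counts are within 1 of the ideal
make_stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(as.character(y))) {
      idx <- which(as.character(y) == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Build repeated stratified cross-validation fold plans
#'
#' `R` repeats of a stratified `K`-fold partition: within each repeat
#' the test sets partition the cohort and per-fold class proportions are
#' within one sample of the stratified ideal.  Deterministic from
#' `seed`.
#'
#' @param labels Outcome labels, one per sample.
#' @param K Folds per repeat (default 5).
#' @param R Repeats (default 10).
#' @param seed Integer seed.
#' @param sample_ids Optional ids (default `names(labels)` or indices).
#' @return List of `R * K` fold plans, each with `repeat_`, `fold`,
#'   `train_ids`, `test_ids`.
#' @export
make_fold_plans <- function(labels, K = 5L, R = 10L, seed = 1L,
                            sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- names(labels) %||% as.character(seq_along(labels))
  plans <- list()
  for (r in seq_len(R)) {
    folds <- make_stratified_folds(labels, K, child_seed(seed, "fold", r))
    for (k in seq_len(K)) {
      plans[[length(plans) + 1]] <- list(
        repeat_ = r, fold = k,
        train_ids = sample_ids[folds != k],
        test_ids = sample_ids[folds == k])
    }
  }
  plans
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustive evaluation of a hyperparameter grid by inner stratified
#' cross-validated mean AUROC; ties (including duplicated grid rows)
#' resolve to the first grid row.
#'
#' @param X_train,y_train Training data.
#' @param classifier Registry name.
#' @param grid data.frame of hyperparameter combinations (one per row).
#' @param inner_cv Inner folds (default 5).
#' @param seed Integer seed.
#' @param sampler Optional sampler name applied inside each inner
#'   training split (never to the inner test split).
#' @return List with `params` (winning row as a list), `mean_auroc`,
#'   and the per-row `scores`.
#' @export
tune_hyperparameters <- function(X_train, y_train, classifier, grid,
                                 inner_cv = 5L, seed = 1L, sampler = "none") {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0) grid <- data.frame()[1, , drop = FALSE]
  if (nrow(grid) == 1) {
    return(list(params = as.list(grid[1, , drop = FALSE]),
                mean_auroc = NA_real_, scores = NA_real_))
  }
  folds <- make_stratified_folds(y_train, inner_cv, child_seed(seed, "tune"))
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, , drop = FALSE])
    aucs <- vapply(seq_len(inner_cv), function(f) {
      tr <- folds != f
      if (length(unique(y_train[tr])) < 2 ||
          length(unique(y_train[!tr])) < 2) return(NA_real_)
      Xtr <- X_train[tr, , drop = FALSE]; ytr <- y_train[tr]
      if (sampler != "none") {
        rs <- apply_sampler(sampler, Xtr, ytr,
                            seed = child_seed(seed, "tunesamp", g, f))
        Xtr <- rs$X; ytr <- rs$y
      }
      fit <- fit_classifier(classifier, Xtr, ytr, params,
                            seed = child_seed(seed, "tunefit", g, f))
      auroc(y_train[!tr] == positive_class(y_train),
            predict_prob(fit, X_train[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which(scores == max(scores, na.rm = TRUE))[1]
  list(params = as.list(grid[best, , drop = FALSE]),
       mean_auroc = scores[best], scores = scores)
}

#' Run the discovery pipeline
#'
#' The core driver: for each of the `R * K` fold plans, using training
#' data only — recompute DEGs, run the three selectors, pool with DEGs
#' and the clinical covariate, reduce by RFE, balance with the
#' configured sampler, tune by inner-CV grid search, fit, and score on
#' the untouched test fold.  Features surviving RFE are tallied into the
#' stability report; per-iteration metrics are aggregated into the CV
#' report.  Every stochastic step is seeded from
#' `(config$seed, repeat, fold)`.
#'
#' @param mat A preprocessed [expression_matrix()] (genes x samples).
#' @param pheno Phenotype table aligned to `colnames(mat)`; its
#'   `severity_score` column (when present) joins the feature matrix as
#'   the clinical covariate.
#' @param config A [run_config()].
#' @param plans Optional precomputed fold plans (as from
#'   [make_fold_plans()]); by default they are derived from the labels
#'   and `config`.  Fixing the plans lets leakage audits poison
#'   test-fold labels without perturbing the partition itself.
#' @return List of class `discovery_result` with `cv_report` (class
#'   `cv_report`) and `stability` (class `stability_report`).
#' @export
run_discovery <- function(mat, pheno, config = run_config(), plans = NULL) {
  stopifnot(identical(colnames(mat), pheno$sample_id))
  labels <- setNames(pheno$outcome, pheno$sample_id)
  clinical <- character(0)
  feat_all <- t(unclass(mat))
  if (!is.null(pheno$severity_score) && !anyNA(pheno$severity_score)) {
    feat_all <- cbind(feat_all, severity_score = pheno$severity_score)
    clinical <- "severity_score"
  }
  plans <- plans %||% make_fold_plans(labels, config$n_folds,
                                      config$n_repeats, config$seed)
  global_degs <- NULL
  if (isTRUE(config$selector_params$global_degs)) {
    d <- select_degs(moderated_t_test(mat, labels), config$fdr_cutoff,
                     config$lfc_cutoff)
    global_degs <- d$top_degs
  }
  grid <- config_grid(config)
  tally <- setNames(numeric(ncol(feat_all)), colnames(feat_all))
  iter_rows <- list()
  fold_logs <- list()

  for (pl in plans) {
    sd_rk <- child_seed(config$seed, pl$repeat_, pl$fold)
    tr_ids <- pl$train_ids; te_ids <- pl$test_ids
    y_tr <- labels[tr_ids]
    if (length(unique(y_tr)) < 2)
      stopf("repeat %d fold %d: training data has a single class",
            pl$repeat_, pl$fold)
    X_tr <- feat_all[tr_ids, , drop = FALSE]

    # (1) per-fold DEG recompute on training samples only
    degs <- global_degs %||% {
      d <- select_degs(moderated_t_test(mat[, tr_ids, drop = FALSE], y_tr),
                       config$fdr_cutoff, config$lfc_cutoff)
      d$top_degs
    }
    gene_cols <- setdiff(colnames(feat_all), clinical)
    Xg <- X_tr[, gene_cols, drop = FALSE]

    # (2) three selectors on training data
    sp <- config$selector_params
    sel_rf <- rf_importance_select(Xg, y_tr, n_trees = sp$rf_trees,
                                   seed = child_seed(sd_rk, "rf"))
    sel_lasso <- lasso_select(Xg, y_tr, seed = child_seed(sd_rk, "lasso"))
    sel_mrmr <- mrmr_select(Xg, y_tr, k = min(sp$mrmr_k, ncol(Xg)))

    # (3) pool + RFE
    pool <- pool_features(list(rf = sel_rf, lasso = sel_lasso,
                               mrmr = sel_mrmr),
                          degs = degs, clinical = clinical)
    selected <- if (length(pool$pooled) <= config$rfe_target) pool$pooled
    else rfe(X_tr, y_tr, pool, estimator = sp$rfe_estimator,
             target = config$rfe_target, step_frac = sp$rfe_step_frac,
             seed = child_seed(sd_rk, "rfe"))
    tally[selected] <- tally[selected] + 1

    # (4) sampler on training fold only
    Xs <- X_tr[, selected, drop = FALSE]
    rs <- apply_sampler(config$sampler, Xs, y_tr,
                        seed = child_seed(sd_rk, "sampler"))

    # (5) tune + fit
    tuned <- tune_hyperparameters(Xs, y_tr, config$classifier, grid,
                                  seed = child_seed(sd_rk, "tune"),
                                  sampler = config$sampler)
    model <- fit_classifier(config$classifier, rs$X, rs$y, tuned$params,
                            seed = child_seed(sd_rk, "fit"))

    # (6) score on the untouched test fold
    scores <- predict_prob(model, feat_all[te_ids, selected, drop = FALSE])
    y_te <- labels[te_ids] == "complicated"
    m <- confusion_metrics(y_te, scores, threshold = 0.5)
    iter_rows[[length(iter_rows) + 1]] <- data.frame(
      repeat_ = pl$repeat_, fold = pl$fold,
      sensitivity = m$sensitivity, specificity = m$specificity,
      fpr = m$fpr, mcc = m$mcc, auroc = auroc(y_te, scores))
    fold_logs[[length(fold_logs) + 1]] <- list(
      repeat_ = pl$repeat_, fold = pl$fold, selected = selected,
      params = tuned$params,
      signature = model_signature(model,
                                  rs$X[seq_len(min(5, nrow(rs$X))), ,
                                       drop = FALSE]))
  }

  iters <- do.call(rbind, iter_rows)
  cv_report <- summarize_cv(iters, config)
  stability <- summarize_stability(tally, config$n_repeats, config$n_folds)
  structure(list(cv_report = cv_report, stability = stability,
                 fold_logs = fold_logs, config = config),
            class = "discovery_result")
}

summarize_cv <- function(iters, config) {
  metrics <- c("sensitivity", "specificity", "fpr", "mcc", "auroc")
  summary <- do.call(rbind, lapply(metrics, function(m) {
    v <- iters[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               lo = quantile(v, 0.025, na.rm = TRUE, names = FALSE),
               hi = quantile(v, 0.975, na.rm = TRUE, names = FALSE))
  }))
  structure(list(iterations = iters, summary = summary,
                 sampler = config$sampler, classifier = config$classifier),
            class = "cv_report")
}

#' Normalized stability scores
#'
#' Converts per-feature selection tallies over the `R * K` CV
#' iterations into normalized scores `100 * count / (R * K)` (percent)
#' and a shortlist of features at or above a threshold.
#'
#' @param tallies Named numeric vector of selection counts.
#' @param R,K Cross-validation geometry.
#' @param threshold_pct Shortlist cutoff in percent (default 60).
#' @return A list of class `stability_report` with `table` (feature,
#'   times_selected, normalized_score, sorted by score then name) and
#'   `shortlist`.
#' @export
summarize_stability <- function(tallies, R, K, threshold_pct = 60) {
  total <- R * K
  if (any(tallies < 0 | tallies > total))
    stopf("tallies must lie in 0..R*K")
  tab <- data.frame(feature = names(tallies),
                    times_selected = as.integer(tallies),
                    normalized_score = 100 * as.numeric(tallies) / total,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$normalized_score, tab$feature), , drop = FALSE]
  rownames(tab) <- NULL
  shortlist <- tab$feature[tab$normalized_score >= threshold_pct &
                             tab$times_selected > 0]
  structure(list(table = tab, shortlist = shortlist, R = R, K = K,
                 threshold_pct = threshold_pct),
            class = "stability_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("CV report: %s-%s, %d iterations\n", x$sampler, x$classifier,
              nrow(x$iterations)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %.3f (%.3f-%.3f)\n", s$metric[i], s$mean[i],
                s$lo[i], s$hi[i]))
  invisible(x)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report over %d iterations (top 10):\n", x$R * x$K))
  print(head(x$table, 10), row.names = FALSE)
  invisible(x)
}

#' Export CV and stability reports as TSV
#'
#' Writes a metrics table shaped `sampler-classifier / Sensitivity (CI)
#' / Specificity (CI) / AUROC (CI) / MCC (CI)` and the stability table.
#'
#' @param result A `discovery_result`.
#' @param dir Output directory.
#' @export
write_discovery_reports <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- result$cv_report$summary
  fmt <- function(m) {
    r <- s[s$metric == m, ]
    sprintf("%.3f (%.3f-%.3f)", r$mean, r$lo, r$hi)
  }
  perf <- data.frame(
    `sampler-classifier` = paste0(toupper(result$config$sampler), "-",
                                  toupper(result$config$classifier)),
    `Sensitivity (CI)` = fmt("sensitivity"),
    `Specificity (CI)` = fmt("specificity"),
    `AUROC (CI)` = fmt("auroc"), `MCC (CI)` = fmt("mcc"),
    check.names = FALSE)
  utils::write.table(perf, file.path(dir, "cv_metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$stability$table,
                     file.path(dir, "stability.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
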