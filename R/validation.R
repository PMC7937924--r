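#' Align a marker panel across two expression platforms
#'
#' Intersects a feature panel with the gene sets of a derivation and a
#' validation matrix.  Errors when too little of the panel survives the
#' intersection (cross-platform validation is meaningless on a sliver
#' of the panel).
#'
#' @param derivation,validation [expression_matrix()] objects.
#' @param panel Character vector of candidate features.
#' @param min_fraction Minimum `|shared| / |panel|` (default 0.5).
#' @return List with `shared` and `dropped` feature vectors.
#' @export
align_features <- function(derivation, validation, panel,
                           min_fraction = 0.5) {
  shared <- panel[panel %in% rownames(derivation) &
                    panel %in% rownames(validation)]
  dropped <- setdiff(panel, shared)
  if (length(shared) == 0)
    stopf("no panel features shared between derivation and validation")
  if (length(shared) / length(panel) < min_fraction)
    stopf("only %d/%d panel features shared (< %.0f%%)",
          length(shared), length(panel), 100 * min_fraction)
  list(shared = shared, dropped = dropped)
}

#' Label a cohort by a severity-score cutoff
#'
#' Surrogate outcome definition for cohorts without a charted
#' complicated-course label: complicated iff the severity score (e.g.
#' APACHE II) meets the cutoff.
#'
#' @param scores Numeric severity scores (no missing values).
#' @param cutoff Threshold (e.g. 25); the protocol sweeps
#'   `c(15, 20, 25, 30)` in sensitivity analyses.
#' @param direction `"ge"` (default, score >= cutoff) or `"gt"`.
#' @return Character vector of `"complicated"`/`"uncomplicated"`.
#' @export
severity_labels <- function(scores, cutoff, direction = c("ge", "gt")) {
  direction <- match.arg(direction)
  if (anyNA(scores)) stopf("severity scores contain missing values")
  hit <- if (direction == "ge") scores >= cutoff else scores > cutoff
  ifelse(hit, "complicated", "uncomplicated")
}

#' Train on derivation, evaluate on an external cohort
#'
#' The external-validation protocol: align the panel across platforms,
#' z-score each gene within each dataset (cross-platform harmonization,
#' disable with `standardize = FALSE`), re-select within the panel on
#' derivation data only (LASSO-based or tree-ranking), balance the
#' derivation set with the configured sampler, tune by inner CV, fit,
#' and score the validation cohort.  Two thresholds are reported: one
#' chosen on derivation data (honest protocol) and the best achievable
#' on the validation scores (labeled post-hoc, for comparability with
#' published tables that select thresholds after the fact).
#'
#' @param derivation,validation Lists with `expr` and `pheno` (as
#'   produced by the generators or the readers).
#' @param panel Character vector of candidate marker genes.
#' @param config A [run_config()].
#' @param reselect `"lasso"` (default) or `"tree"` panel-internal
#'   re-selection; `"none"` keeps the aligned panel.
#' @param standardize Per-gene within-dataset z-scoring (default TRUE).
#' @return List of class `validation_run`: shared/dropped features, the
#'   selected subset, AUROC, and `metrics_honest` /
#'   `metrics_posthoc_best` metric sets.
#' @export
run_validation <- function(derivation, validation, panel,
                           config = run_config(), reselect = "lasso",
                           standardize = TRUE) {
  al <- align_features(derivation$expr, validation$expr, panel)
  Xd <- t(unclass(derivation$expr)[al$shared, , drop = FALSE])
  Xv <- t(unclass(validation$expr)[al$shared, , drop = FALSE])
  if (standardize) {
    Xd <- zscore_cols(Xd)
    Xv <- zscore_cols(Xv)
  }
  yd <- derivation$pheno$outcome
  yv <- validation$pheno$outcome

  subset <- switch(reselect,
    none = al$shared,
    lasso = {
      s <- lasso_select(Xd, yd, seed = child_seed(config$seed, "val", "l"))
      if (length(s) < 2) al$shared else s
    },
    tree = {
      model <- fit_classifier("extratrees", Xd, yd,
                              params = list(n_trees = 250L),
                              seed = child_seed(config$seed, "val", "t"))
      imp <- feature_importance(model)
      names(imp)[imp > mean(imp)]
    },
    stopf("unknown reselect '%s'", reselect))
  Xd_s <- Xd[, subset, drop = FALSE]
  Xv_s <- Xv[, subset, drop = FALSE]

  rs <- apply_sampler(config$sampler, Xd_s, yd,
                      seed = child_seed(config$seed, "val", "s"))
  tuned <- tune_hyperparameters(Xd_s, yd, config$classifier,
                                config_grid(config),
                                seed = child_seed(config$seed, "val", "g"),
                                sampler = config$sampler)
  model <- fit_classifier(config$classifier, rs$X, rs$y, tuned$params,
                          seed = child_seed(config$seed, "val", "f"))

  # honest threshold: best-MCC threshold on derivation training scores
  d_scores <- predict_prob(model, Xd_s)
  thr_honest <- threshold_sweep(yd == "complicated", d_scores,
                                step = config$threshold_step)$best$threshold

  v_scores <- predict_prob(model, Xv_s)
  yv_bin <- yv == "complicated"
  auc <- if (length(unique(yv_bin)) < 2) NA_real_ else auroc(yv_bin, v_scores)
  metrics_honest <- confusion_metrics(yv_bin, v_scores, thr_honest)
  metrics_posthoc <- if (length(unique(yv_bin)) < 2) NULL
    else threshold_sweep(yv_bin, v_scores, step = config$threshold_step)$best

  structure(list(shared_features = al$shared,
                 dropped_features = al$dropped,
                 selected_subset = subset,
                 sampler = config$sampler, classifier = config$classifier,
                 params = tuned$params, auroc = auc,
                 threshold_honest = thr_honest,
                 metrics_honest = metrics_honest,
                 metrics_posthoc_best = metrics_posthoc,
                 model = model, validation_scores = v_scores),
            class = "validation_run")
}

#' @export
print.validation_run <- function(x, ...) {
  cat(sprintf("External validation: %s-%s, %d/%d panel features used\n",
              x$sampler, x$classifier, length(x$selected_subset),
              length(x$shared_features) + length(x$dropped_features)))
  cat(sprintf("  AUROC %.3f; honest threshold %.3f (sens %.3f, spec %.3f)\n",
              x$auroc, x$threshold_honest, x$metrics_honest$sensitivity,
              x$metrics_honest$specificity))
  if (!is.null(x$metrics_posthoc_best))
    cat(sprintf("  post-hoc best threshold %.3f (MCC %.3f)\n",
                x$metrics_posthoc_best$threshold, x$metrics_posthoc_best$mcc))
  invisible(x)
}
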