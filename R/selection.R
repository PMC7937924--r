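#' Random-forest importance selection
#'
#' Ranks features by impurity-decrease importance from a random forest
#' and selects either every feature with importance above the mean
#' (capped at `cap`) or the top `k`.
#'
#' @param X Numeric matrix (samples x features, named columns).
#' @param y Outcome labels.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @param rule `"above_mean"` (default) or `"top_k"`.
#' @param k Used by `rule = "top_k"`.
#' @param cap Maximum selected under `"above_mean"` (default 200).
#' @return Character vector of selected feature names, importance-ranked.
#' @export
rf_importance_select <- function(X, y, n_trees = 500L, seed = 1L,
                                 rule = c("above_mean", "top_k"), k = 50L,
                                 cap = 200L) {
  rule <- match.arg(rule)
  if (ncol(X) < 2) stopf("need >= 2 features")
  model <- fit_classifier("rf", X, y,
                          params = list(n_trees = n_trees, min_leaf = 5L),
                          seed = seed)
  imp <- feature_importance(model)
  ord <- order(-imp, names(imp))
  sel <- if (rule == "above_mean") {
    keep <- names(imp)[imp > mean(imp)]
    head(names(imp)[ord][names(imp)[ord] %in% keep], cap)
  } else {
    head(names(imp)[ord], k)
  }
  sel
}

#' LASSO selection
#'
#' L1-penalized logistic regression on internally standardized features;
#' the penalty is chosen by 5-fold cross-validation (binomial deviance,
#' 1-SE rule), and the features with nonzero coefficients at that
#' penalty are returned.  Deviance rather than AUROC scores the penalty
#' path because only a proper scoring rule keeps null selections empty.
#'
#' @inheritParams rf_importance_select
#' @export
lasso_select <- function(X, y, seed = 1L) {
  Xs <- zscore_cols(X)
  model <- fit_classifier("lasso", Xs, y, params = list(lambda = NA),
                          seed = seed)
  co <- feature_importance(model)
  names(co)[co > 0]
}

#' Minimum-redundancy maximum-relevance selection
#'
#' Greedy forward selection under the F-statistic/correlation difference
#' scheme: relevance is the class-wise one-way F statistic (scaled to
#' `[0, 1]` by its maximum so the difference with a correlation is on a
#' meaningful scale), redundancy the mean absolute Pearson correlation
#' with the already-selected set, and each step adds
#' `argmax(relevance_j - redundancy_j)`.  A candidate perfectly
#' correlated with an already-selected feature is never added while any
#' other candidate remains.  Ties break by feature name.
#'
#' @inheritParams rf_importance_select
#' @param k Number of features to select (`k <= ncol(X)`).
#' @export
mrmr_select <- function(X, y, k) {
  if (k > ncol(X)) stopf("k must be <= number of features")
  pos <- y == positive_class(y)
  f_rel <- f_statistic(X, pos)
  if (max(f_rel) > 0) f_rel <- f_rel / max(f_rel)
  feats <- colnames(X)
  selected <- character(0)
  remaining <- feats
  red_sum <- setNames(numeric(length(feats)), feats)
  red_max <- setNames(numeric(length(feats)), feats)
  for (step in seq_len(k)) {
    score <- if (length(selected) == 0) f_rel[remaining]
             else f_rel[remaining] - red_sum[remaining] / length(selected)
    # exact duplicates of a selected feature go last, never first
    dup <- red_max[remaining] >= 1 - 1e-12
    if (any(dup) && !all(dup)) score[dup] <- -Inf
    # argmax with ties broken by name
    best <- remaining[order(-score, remaining)][1]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining)) {
      r <- abs(suppressWarnings(cor(X[, remaining, drop = FALSE], X[, best])))
      r[is.na(r)] <- 0
      red_sum[remaining] <- red_sum[remaining] + as.numeric(r)
      red_max[remaining] <- pmax(red_max[remaining], as.numeric(r))
    }
  }
  selected
}

# one-way two-group F statistic per feature (equals pooled t^2)
f_statistic <- function(X, pos) {
  n1 <- sum(pos); n0 <- sum(!pos); n <- n1 + n0
  m1 <- colMeans(X[pos, , drop = FALSE])
  m0 <- colMeans(X[!pos, , drop = FALSE])
  mg <- colMeans(X)
  ssb <- n1 * (m1 - mg)^2 + n0 * (m0 - mg)^2
  ssw <- colSums((X[pos, , drop = FALSE] -
                    matrix(m1, n1, ncol(X), byrow = TRUE))^2) +
    colSums((X[!pos, , drop = FALSE] -
               matrix(m0, n0, ncol(X), byrow = TRUE))^2)
  f <- ssb / pmax(ssw / (n - 2), 1e-12)
  setNames(f, colnames(X))
}

#' Pool candidate features
#'
#' Union of the per-method selections, the DEG list and the clinical
#' covariates, in a deterministic order: clinical first, then DEGs, then
#' the method lists (rf, lasso, mrmr), alphabetical within each block,
#' first occurrence wins.  Clinical features are always retained through
#' pooling (and are exempt from RFE by default).
#'
#' @param selections Named list of character vectors (`rf`, `lasso`,
#'   `mrmr`).
#' @param degs Character vector of DEG names.
#' @param clinical Character vector of clinical covariate names.
#' @return A list of class `feature_pool` with the per-source lists and
#'   `pooled`.
#' @export
pool_features <- function(selections, degs = character(0),
                          clinical = character(0)) {
  blocks <- c(list(clinical = sort(unique(clinical)),
                   deg = sort(unique(degs))),
              lapply(selections[order(match(names(selections),
                                            c("rf", "lasso", "mrmr")))],
                     function(v) sort(unique(v))))
  pooled <- character(0)
  for (b in blocks) pooled <- c(pooled, setdiff(b, pooled))
  structure(list(rf = selections$rf %||% character(0),
                 lasso = selections$lasso %||% character(0),
                 mrmr = selections$mrmr %||% character(0),
                 deg = degs, clinical = clinical, pooled = pooled),
            class = "feature_pool")
}

#' Recursive feature elimination
#'
#' Iteratively fits the estimator on the current feature set, ranks
#' features by [feature_importance()], and drops the
#' `ceiling(step_frac * current)` lowest-ranked (never below `target`,
#' never a clinical feature unless `protect_clinical = FALSE`), stopping
#' when `target` features remain.
#'
#' @param X Numeric matrix containing at least the pooled features.
#' @param y Outcome labels.
#' @param pool A [pool_features()] result (or character vector).
#' @param estimator Classifier registry name used for ranking.  The
#'   default is `"extratrees"`: random-cutpoint importances suffer less
#'   from the masking bias of bootstrap forests, which otherwise lets a
#'   lucky noise feature displace a weak-but-real marker.
#' @param target Number of features to retain.
#' @param step_frac Fraction of the current set dropped per iteration.
#' @param seed Integer seed.
#' @param params Estimator hyperparameters.
#' @param protect_clinical Exempt the pool's clinical features from
#'   elimination (default TRUE).
#' @return Character vector of `target` feature names.
#' @export
rfe <- function(X, y, pool, estimator = "extratrees", target = 20L,
                step_frac = 0.1, seed = 1L,
                params = list(n_trees = 500L, min_leaf = 5L),
                protect_clinical = TRUE) {
  features <- if (inherits(pool, "feature_pool")) pool$pooled else pool
  clinical <- if (inherits(pool, "feature_pool") && protect_clinical)
    pool$clinical else character(0)
  missing <- setdiff(features, colnames(X))
  if (length(missing)) stopf("pool feature absent from X: %s", missing[1])
  if (target > length(features)) stopf("target exceeds pool size")
  current <- features
  it <- 0L
  while (length(current) > target) {
    it <- it + 1L
    model <- fit_classifier(estimator, X[, current, drop = FALSE], y,
                            params = params,
                            seed = child_seed(seed, "rfe", it))
    imp <- feature_importance(model)
    n_drop <- min(ceiling(step_frac * length(current)),
                  length(current) - target)
    droppable <- setdiff(names(sort(imp, decreasing = FALSE)), clinical)
    # ties in importance resolve by name via stable ordering
    ord <- order(imp[droppable], droppable)
    drop <- droppable[ord][seq_len(min(n_drop, length(droppable)))]
    if (!length(drop)) break
    current <- setdiff(current, drop)
  }
  current
}
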