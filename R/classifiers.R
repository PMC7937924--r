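#' Classifier registry
#'
#' All classifiers share one contract: `fit_classifier(name, X, y,
#' params, seed)` returns a fitted model and `predict_prob(model, X)`
#' returns the predicted probability of the positive class
#' (`"complicated"`).  Registered names:
#'
#' * `"logit"` — ridge-penalized logistic regression (`lambda`).
#' * `"rf"` — plain bootstrap random forest (used by the importance
#'   selector; not balanced).
#' * `"lasso"` — L1-penalized logistic regression; `lambda = NA` picks
#'   the penalty by internal 5-fold cross-validated AUROC.
#' * `"brf"` — balanced random forest: each bootstrap sample is randomly
#'   undersampled to class balance before tree growth (`n_trees`,
#'   `max_depth` with 0 = unlimited, `mtry`).
#' * `"extratrees"` — extremely randomized trees: random cutpoints, no
#'   bootstrap.
#' * `"gbm"` — stagewise gradient boosting with logistic loss and
#'   shallow regression trees (`n_trees`, `shrinkage`, `max_depth`).
#' * `"easy_ensemble"` — ensemble of boosted learners, each trained on
#'   an independently random-undersampled balanced sample
#'   (`n_members`).
#' * `"stack_brf_logit"`, `"stack_brf_et"`, `"stack_brf_gbm_et"` —
#'   soft-voting stacks averaging member probabilities.
#'
#' @param name Registry name.
#' @param X Numeric matrix (samples x features).
#' @param y Outcome labels.
#' @param params Named list of hyperparameters (see above).
#' @param seed Integer seed.
#' @return An object of class `sepstab_model`.
#' @export
fit_classifier <- function(name, X, y, params = list(), seed = 1L) {
  X <- as.matrix(X)
  pos <- positive_class(y)
  yb <- as.numeric(y == pos)
  if (length(unique(yb)) < 2) stopf("training data has a single class")
  fit <- with_seed(seed, switch(name,
    logit = fit_glmnet(X, yb, alpha = 0, lambda = params$lambda %||% 1),
    lasso = fit_lasso(X, yb, params$lambda, seed),
    rf = fit_forest(X, yb, params, balanced = FALSE, bootstrap = TRUE,
                    extra = FALSE),
    brf = fit_forest(X, yb, params, balanced = TRUE, bootstrap = TRUE,
                     extra = FALSE),
    extratrees = fit_forest(X, yb, params, balanced = FALSE,
                            bootstrap = FALSE, extra = TRUE),
    gbm = fit_gbm(X, yb, params),
    easy_ensemble = fit_easy_ensemble(X, yb, params, seed),
    stack_brf_logit = fit_stack(X, yb, c("brf", "logit"), params, seed),
    stack_brf_et = fit_stack(X, yb, c("brf", "extratrees"), params, seed),
    stack_brf_gbm_et = fit_stack(X, yb, c("brf", "gbm", "extratrees"),
                                 params, seed),
    stopf("unknown classifier '%s'", name)))
  structure(list(name = name, fit = fit, positive = pos,
                 features = colnames(X), params = params),
            class = "sepstab_model")
}

#' @rdname fit_classifier
#' @param model A `sepstab_model`.
#' @export
predict_prob <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(model$features) && !is.null(colnames(X)))
    X <- X[, model$features, drop = FALSE]
  f <- model$fit
  p <- switch(f$kind,
    glmnet = as.numeric(predict(f$obj, if (isTRUE(f$pad)) pad1(X) else X,
                                s = f$lambda, type = "response")),
    forest = cpp_forest_predict(f$obj$trees, X),
    gbm = predict_gbm(f, X),
    ensemble = rowMeans(vapply(f$members, function(m) predict_prob(m, X),
                               numeric(nrow(X)))))
  pmin(pmax(p, 0), 1)
}

positive_class <- function(y) {
  u <- unique(as.character(y))
  if ("complicated" %in% u) "complicated" else sort(u)[length(u)]
}

pad1 <- function(X) cbind(X, ..pad = 0) # glmnet needs >= 2 columns

fit_glmnet <- function(X, yb, alpha, lambda) {
  pad <- ncol(X) < 2
  if (pad) X <- pad1(X)
  obj <- glmnet::glmnet(X, yb, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = TRUE)
  list(kind = "glmnet", obj = obj, lambda = lambda, pad = pad)
}

fit_lasso <- function(X, yb, lambda, seed) {
  pad <- ncol(X) < 2
  if (pad) X <- pad1(X)
  if (is.null(lambda) || is.na(lambda)) {
    foldid <- make_stratified_folds(yb, 5L, child_seed(seed, "lassocv"))
    # binomial deviance + 1-SE rule: a proper scoring rule whose
    # cross-validation curve is null-calibrated, so label-independent
    # data yields (near-)empty selections; AUROC-scored CV is
    # optimistically biased over the penalty path and is not
    cvfit <- suppressWarnings(
      glmnet::cv.glmnet(X, yb, family = "binomial", alpha = 1,
                        foldid = foldid, type.measure = "deviance"))
    lambda <- cvfit$lambda.1se
    list(kind = "glmnet", obj = cvfit$glmnet.fit, lambda = lambda, pad = pad)
  } else {
    obj <- glmnet::glmnet(X, yb, family = "binomial", alpha = 1,
                          lambda = lambda, standardize = TRUE)
    list(kind = "glmnet", obj = obj, lambda = lambda, pad = pad)
  }
}

fit_forest <- function(X, yb, params, balanced, bootstrap, extra) {
  n_trees <- params$n_trees %||% 200L
  max_depth <- params$max_depth %||% 0L
  mtry <- params$mtry %||% max(1L, floor(sqrt(ncol(X))))
  min_leaf <- params$min_leaf %||% 1L
  obj <- cpp_forest_fit(X, yb, as.integer(n_trees), as.integer(mtry),
                        as.integer(max_depth), as.integer(min_leaf),
                        balanced, bootstrap, params$sample_frac %||% 1.0,
                        extra)
  list(kind = "forest", obj = obj)
}

# Stagewise logistic gradient boosting: regression trees are fitted to
# the negative gradient (y - p) and terminal-node values replaced by the
# Newton step sum(r) / sum(p (1-p)).
fit_gbm <- function(X, yb, params) {
  n_trees <- params$n_trees %||% 100L
  shrinkage <- params$shrinkage %||% 0.1
  max_depth <- params$max_depth %||% 2L
  n <- nrow(X)
  pbar <- mean(yb)
  f0 <- log(pbar / (1 - pbar))
  Fx <- rep(f0, n)
  trees <- vector("list", n_trees)
  leaf_vals <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    p <- 1 / (1 + exp(-Fx))
    r <- yb - p
    ft <- cpp_tree_fit(X, r, ncol(X), as.integer(max_depth), 5L)
    w <- pmax(p * (1 - p), 1e-6)
    num <- rowsum(r, ft$leaf)
    den <- rowsum(w, ft$leaf)
    gamma <- setNames(as.numeric(num / den), rownames(num))
    trees[[t]] <- ft$tree
    leaf_vals[[t]] <- gamma
    Fx <- Fx + shrinkage * gamma[as.character(ft$leaf)]
  }
  list(kind = "gbm", trees = trees, leaf_vals = leaf_vals, f0 = f0,
       shrinkage = shrinkage)
}

predict_gbm <- function(f, X) {
  Fx <- rep(f$f0, nrow(X))
  for (t in seq_along(f$trees)) {
    leaf <- cpp_tree_leaf(f$trees[[t]], X)
    Fx <- Fx + f$shrinkage * f$leaf_vals[[t]][as.character(leaf)]
  }
  1 / (1 + exp(-Fx))
}

fit_easy_ensemble <- function(X, yb, params, seed) {
  n_members <- params$n_members %||% 10L
  members <- lapply(seq_len(n_members), function(m) {
    rs <- random_undersample(X, yb, seed = child_seed(seed, "ee", m))
    fit_classifier("gbm", rs$X, rs$y,
                   params = list(n_trees = params$n_trees %||% 50L,
                                 max_depth = 1L),
                   seed = child_seed(seed, "eem", m))
  })
  list(kind = "ensemble", members = members)
}

fit_stack <- function(X, yb, members, params, seed) {
  fits <- lapply(seq_along(members), function(i) {
    fit_classifier(members[[i]], X, yb, params = list(),
                   seed = child_seed(seed, "stack", i))
  })
  list(kind = "ensemble", members = fits)
}

#' Model-based feature importance
#'
#' Importance used by recursive feature elimination: impurity decrease
#' for tree ensembles, absolute standardized coefficients for penalized
#' logistic models, summed split gains for boosting, member average for
#' ensembles.
#'
#' @param model A `sepstab_model`.
#' @return Named numeric vector over `model$features`.
#' @export
feature_importance <- function(model) {
  f <- model$fit
  imp <- switch(f$kind,
    glmnet = {
      co <- as.numeric(coef(f$obj, s = f$lambda))[-1]
      if (isTRUE(f$pad)) co <- co[-length(co)]
      abs(co)
    },
    forest = as.numeric(f$obj$importance),
    gbm = {
      acc <- numeric(length(model$features))
      for (t in seq_along(f$trees)) {
        tr <- f$trees[[t]]
        internal <- tr[, "feature"] >= 0
        if (any(internal)) {
          tab <- rowsum(tr[internal, "n"], tr[internal, "feature"])
          acc[as.integer(rownames(tab)) + 1] <-
            acc[as.integer(rownames(tab)) + 1] + as.numeric(tab)
        }
      }
      acc
    },
    ensemble = {
      rowMeans(vapply(f$members, function(m) {
        v <- feature_importance(m)
        v / max(sum(v), 1e-12)
      }, numeric(length(model$features))))
    })
  setNames(imp, model$features)
}

# deterministic fingerprint of a fitted model, used by the leakage tests
model_signature <- function(model, X_probe) {
  unname(round(predict_prob(model, X_probe), 12))
}

#' Per-tree bag class counts of a balanced random forest
#'
#' Exposes, for every tree in a `"brf"` (or any forest) model, the
#' number of negative/positive instances in its bootstrap bag — the
#' balanced-random-forest contract is that these are equal for every
#' tree.
#'
#' @param model A forest-backed `sepstab_model`.
#' @return Integer matrix (trees x 2), columns `neg`, `pos`.
#' @export
bag_class_counts <- function(model) {
  if (model$fit$kind != "forest") stopf("not a forest model")
  m <- model$fit$obj$bag_counts
  colnames(m) <- c("neg", "pos")
  m
}
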