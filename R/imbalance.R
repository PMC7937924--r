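#' Class-imbalance resampling
#'
#' Six resampling schemes for balancing a training set before
#' classification, each returning a `resample_result`: the resampled
#' feature matrix and labels, per-row provenance (`original` vs
#' `synthetic`, with source indices for synthetic rows), the indices
#' removed by undersampling, and before/after class counts.  Samplers
#' are meant to be applied inside training folds only — never to test
#' folds.
#'
#' @name imbalance
#' @param X Numeric feature matrix (samples x features).
#' @param y Outcome labels; the minority/majority split is taken from
#'   the observed counts.
#' @param seed Integer seed.
#' @return A list of class `resample_result` with `X`, `y`, `origin`,
#'   `source` (synthetic rows' parent indices), `removed`,
#'   `counts_before`, `counts_after`.
NULL

resample_result <- function(X, y, origin, source, removed, y_in, extra = list()) {
  structure(c(list(X = X, y = y, origin = origin, source = source,
                   removed = removed,
                   counts_before = table(y_in), counts_after = table(y)),
              extra),
            class = "resample_result")
}

split_classes <- function(y) {
  tab <- table(y)
  if (length(tab) != 2) stopf("resampling needs exactly two classes")
  minority <- names(tab)[which.min(tab)]
  list(minority = minority, majority = setdiff(names(tab), minority),
       n_min = min(tab), n_maj = max(tab))
}

#' @describeIn imbalance Synthetic minority oversampling: each synthetic
#'   row is `a + u (b - a)` with `u ~ U(0, 1)` and `b` one of `a`'s `k`
#'   nearest minority neighbours (Euclidean); synthesis continues until
#'   `minority / majority == target_ratio`.
#' @param k Number of nearest neighbours (default 5; lowered with a
#'   warning when the minority class is too small).
#' @param target_ratio Desired minority/majority ratio (default 1).
#' @export
smote <- function(X, y, k = 5L, target_ratio = 1.0, seed = 1L) {
  cls <- split_classes(y)
  min_idx <- which(y == cls$minority)
  if (length(min_idx) <= k) {
    k <- length(min_idx) - 1L
    warnf("minority count <= k; lowering k to %d", k)
  }
  if (k < 1) stopf("minority class too small for SMOTE")
  n_needed <- round(target_ratio * cls$n_maj) - cls$n_min
  if (n_needed <= 0) {
    return(resample_result(X, y, rep("original", nrow(X)),
                           rep(NA_integer_, nrow(X)), integer(0), y))
  }
  Xmin <- X[min_idx, , drop = FALSE]
  nn <- FNN::get.knn(Xmin, k = k)$nn.index
  with_seed(seed, {
    a <- sample.int(length(min_idx), n_needed, replace = TRUE)
    b <- nn[cbind(a, sample.int(k, n_needed, replace = TRUE))]
    u <- runif(n_needed)
    synth <- Xmin[a, , drop = FALSE] +
      u * (Xmin[b, , drop = FALSE] - Xmin[a, , drop = FALSE])
  })
  X_out <- rbind(X, synth)
  y_out <- c(y, rep(cls$minority, n_needed))
  resample_result(X_out, y_out,
                  c(rep("original", nrow(X)), rep("synthetic", n_needed)),
                  c(rep(NA_integer_, nrow(X)), min_idx[a]),
                  integer(0), y)
}

#' @describeIn imbalance Random undersampling: the majority class is
#'   subsampled without replacement to the minority size.
#' @export
random_undersample <- function(X, y, seed = 1L) {
  cls <- split_classes(y)
  maj_idx <- which(y == cls$majority)
  keep <- with_seed(seed, sort(sample(maj_idx, cls$n_min)))
  sel <- sort(c(which(y == cls$minority), keep))
  resample_result(X[sel, , drop = FALSE], y[sel],
                  rep("original", length(sel)),
                  rep(NA_integer_, length(sel)),
                  setdiff(maj_idx, keep), y)
}

#' @describeIn imbalance Cluster-centroid undersampling: k-means with
#'   `k = minority count` on the majority class, whose rows are replaced
#'   by the `k` centroids (set `keep_nearest_instances = TRUE` to keep
#'   the original instance nearest each centroid instead).
#' @param keep_nearest_instances Keep nearest real instances instead of
#'   the centroids themselves.
#' @export
cluster_centroids <- function(X, y, seed = 1L, keep_nearest_instances = FALSE) {
  cls <- split_classes(y)
  maj_idx <- which(y == cls$majority)
  min_idx <- which(y == cls$minority)
  Xmaj <- X[maj_idx, , drop = FALSE]
  k <- cls$n_min
  uniq <- unique(Xmaj)
  centroids <- if (nrow(uniq) <= k) {
    # degenerate: fewer distinct points than requested centroids
    uniq[rep(seq_len(nrow(uniq)), length.out = k), , drop = FALSE]
  } else {
    with_seed(seed, kmeans(Xmaj, centers = k, nstart = 5,
                           iter.max = 50)$centers)
  }
  if (keep_nearest_instances) {
    nearest <- FNN::get.knnx(Xmaj, centroids, k = 1)$nn.index[, 1]
    keep <- maj_idx[unique(nearest)]
    sel <- sort(c(min_idx, keep))
    return(resample_result(X[sel, , drop = FALSE], y[sel],
                           rep("original", length(sel)),
                           rep(NA_integer_, length(sel)),
                           setdiff(maj_idx, keep), y))
  }
  X_out <- rbind(X[min_idx, , drop = FALSE], unname(centroids))
  y_out <- c(y[min_idx], rep(cls$majority, k))
  resample_result(X_out, y_out,
                  c(rep("original", length(min_idx)), rep("synthetic", k)),
                  rep(NA_integer_, length(min_idx) + k),
                  maj_idx, y)
}

#' @describeIn imbalance Edited nearest neighbours: every majority-class
#'   instance whose `k` nearest neighbours (excluding itself) vote
#'   against its label — i.e. at least half of them belong to the other
#'   class — is discarded.  `symmetric = TRUE` cleans both classes.
#' @param symmetric Clean both classes rather than the majority only.
#' @export
enn <- function(X, y, k = 3L, symmetric = FALSE) {
  if (nrow(X) <= k) stopf("need more than k samples")
  cls <- split_classes(y)
  nn <- FNN::get.knn(X, k = k)$nn.index
  disagree <- vapply(seq_len(nrow(X)), function(i) {
    sum(y[nn[i, ]] != y[i])
  }, numeric(1))
  flagged <- 2 * disagree >= k
  removable <- if (symmetric) flagged else flagged & y == cls$majority
  keep <- which(!removable)
  resample_result(X[keep, , drop = FALSE], y[keep],
                  rep("original", length(keep)),
                  rep(NA_integer_, length(keep)),
                  which(removable), y)
}

#' @describeIn imbalance Repeated ENN: [enn()] applied successively
#'   until no further instances can be removed (or `max_iter` is hit);
#'   the iteration count is reported in the result as `iterations`.
#' @param max_iter Iteration cap for RENN (default 100).
#' @export
renn <- function(X, y, k = 3L, max_iter = 100L, symmetric = FALSE) {
  removed_abs <- integer(0)
  idx_map <- seq_len(nrow(X))
  Xc <- X; yc <- y
  iters <- 0L
  for (i in seq_len(max_iter)) {
    cls_n <- table(yc)
    if (length(cls_n) < 2 || nrow(Xc) <= k) break
    step <- enn(Xc, yc, k = k, symmetric = symmetric)
    if (length(step$removed) == 0) break
    iters <- iters + 1L
    removed_abs <- c(removed_abs, idx_map[step$removed])
    keep <- setdiff(seq_len(nrow(Xc)), step$removed)
    idx_map <- idx_map[keep]
    Xc <- Xc[keep, , drop = FALSE]; yc <- yc[keep]
  }
  resample_result(Xc, yc, rep("original", nrow(Xc)),
                  rep(NA_integer_, nrow(Xc)), sort(removed_abs), y,
                  extra = list(iterations = iters))
}

#' @describeIn imbalance Instance-hardness-threshold undersampling:
#'   hardness is one minus the out-of-fold predicted probability of the
#'   true class under cross-validated fits of `estimator`; majority
#'   instances with the highest hardness are removed until the classes
#'   balance.
#' @param estimator Classifier registry name used to score hardness
#'   (default `"logit"`).
#' @param cv Number of cross-validation folds for the hardness scores.
#' @export
instance_hardness_threshold <- function(X, y, estimator = "logit", cv = 5L,
                                        seed = 1L) {
  cls <- split_classes(y)
  n <- nrow(X)
  folds <- make_stratified_folds(y, cv, child_seed(seed, "iht"))
  p_pos <- numeric(n)
  for (f in seq_len(cv)) {
    test <- folds == f
    fit <- fit_classifier(estimator, X[!test, , drop = FALSE], y[!test],
                          params = list(), seed = child_seed(seed, "iht", f))
    p_pos[test] <- predict_prob(fit, X[test, , drop = FALSE])
  }
  p_true <- ifelse(y == positive_class(y), p_pos, 1 - p_pos)
  hardness <- 1 - p_true
  maj_idx <- which(y == cls$majority)
  n_remove <- cls$n_maj - cls$n_min
  # hardest majority instances go first; ties broken by index order
  ord <- maj_idx[order(-hardness[maj_idx], maj_idx)]
  removed <- sort(ord[seq_len(n_remove)])
  keep <- setdiff(seq_len(n), removed)
  resample_result(X[keep, , drop = FALSE], y[keep],
                  rep("original", length(keep)),
                  rep(NA_integer_, length(keep)), removed, y)
}

#' Apply a named sampler
#'
#' Dispatch helper used by the cross-validation driver; `"none"` is the
#' identity.
#'
#' @param name Sampler name: one of `"smote"`, `"rus"`, `"ccn"`,
#'   `"enn"`, `"renn"`, `"iht"`, `"none"`.
#' @inheritParams imbalance
#' @export
apply_sampler <- function(name, X, y, seed = 1L) {
  switch(name,
    none = resample_result(X, y, rep("original", nrow(X)),
                           rep(NA_integer_, nrow(X)), integer(0), y),
    smote = smote(X, y, seed = seed),
    rus = random_undersample(X, y, seed = seed),
    ccn = cluster_centroids(X, y, seed = seed),
    enn = enn(X, y),
    renn = renn(X, y),
    iht = instance_hardness_threshold(X, y, seed = seed),
    stopf("unknown sampler '%s'", name))
}
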