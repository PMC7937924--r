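#' Confusion-matrix metrics at a threshold
#'
#' Scores strictly greater than the threshold are called positive
#' (complicated).  Returns sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, false positive rate `FP/(FP+TN)`, and the Matthews
#' correlation coefficient
#' `(TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Metrics with a zero denominator are reported as `NA` and named in
#' `undefined` rather than silently propagating `NaN`.
#'
#' @param y_true Logical/binary truth (positive = complicated).
#' @param y_score Scores in `[0, 1]`.
#' @param threshold Classification threshold in `[0, 1]`.
#' @return A list of class `metric_set`.
#' @export
confusion_metrics <- function(y_true, y_score, threshold = 0.5) {
  y_true <- as_binary(y_true)
  if (any(y_score < 0 | y_score > 1)) stopf("scores must lie in [0, 1]")
  pred <- y_score > threshold
  tp <- sum(pred & y_true == 1); tn <- sum(!pred & y_true == 0)
  fp <- sum(pred & y_true == 0); fn <- sum(!pred & y_true == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  fpr <- safe_div(fp, fp + tn)
  mcc_den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  und <- c("sensitivity", "specificity", "fpr",
           "mcc")[c(is.na(sens), is.na(spec), is.na(fpr), is.na(mcc))]
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec, fpr = fpr,
                 mcc = mcc, threshold = threshold, undefined = und),
            class = "metric_set")
}

as_binary <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) return(as.integer(y != 0))
  as.integer(y == positive_class(y))
}

#' Area under the ROC curve
#'
#' The Mann-Whitney rank formulation: the probability that a random
#' positive scores above a random negative, with ties credited 0.5.
#'
#' @inheritParams confusion_metrics
#' @return AUROC in `[0, 1]`; `NA` when a class is absent.
#' @export
auroc <- function(y_true, y_score) {
  y_true <- as_binary(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold sweep
#'
#' Evaluates [confusion_metrics()] on the grid `{0, step, ..., 1}` and
#' returns the best threshold by the chosen criterion (maximum MCC, or
#' maximum Youden J = sensitivity + specificity - 1), ties resolved to
#' the lowest threshold, together with the full sweep table.
#'
#' @inheritParams confusion_metrics
#' @param step Grid step; must divide 1 evenly (default 0.001, i.e.
#'   1001 thresholds).
#' @param criterion `"max_mcc"` (default) or `"max_youden"`.
#' @return List with `best` (a `metric_set`) and `sweep` (data.frame).
#' @export
threshold_sweep <- function(y_true, y_score, step = 0.001,
                            criterion = c("max_mcc", "max_youden")) {
  criterion <- match.arg(criterion)
  nsteps <- 1 / step
  if (abs(nsteps - round(nsteps)) > 1e-8)
    stopf("step must divide 1 into an integer number of steps")
  thresholds <- (0:round(nsteps)) / round(nsteps)
  rows <- lapply(thresholds, function(th) {
    m <- confusion_metrics(y_true, y_score, th)
    data.frame(threshold = th, tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
               sensitivity = m$sensitivity, specificity = m$specificity,
               fpr = m$fpr, mcc = m$mcc)
  })
  sweep_tab <- do.call(rbind, rows)
  score <- if (criterion == "max_mcc") sweep_tab$mcc
           else sweep_tab$sensitivity + sweep_tab$specificity - 1
  score[is.na(score)] <- -Inf
  best_i <- which(score == max(score))[1] # lowest threshold wins ties
  list(best = confusion_metrics(y_true, y_score, thresholds[best_i]),
       sweep = sweep_tab)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum absolute difference between the two empirical
#' CDFs, evaluated at all observed points; the p-value comes from the
#' asymptotic Kolmogorov distribution at effective size
#' `n1 n2 / (n1 + n2)`.
#'
#' @param x,y Numeric samples (each nonempty).
#' @return A list of class `ks_result` with `statistic`, `p_value`,
#'   `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stopf("both samples must be nonempty")
  pts <- sort(unique(c(x, y)))
  cdf1 <- vapply(pts, function(t) mean(x <= t), numeric(1))
  cdf2 <- vapply(pts, function(t) mean(y <= t), numeric(1))
  D <- max(abs(cdf1 - cdf2))
  ne <- n1 * n2 / (n1 + n2)
  p <- kolmogorov_sf(sqrt(ne) * D)
  structure(list(statistic = D, p_value = p, n1 = n1, n2 = n2,
                 bootstrap_mean = NULL, n_boot = 0L),
            class = "ks_result")
}

# survival function of the Kolmogorov distribution, 2 sum (-1)^(j-1) exp(-2 j^2 t^2)
kolmogorov_sf <- function(t) {
  if (t <= 0) return(1)
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t^2))
  min(max(p, 0), 1)
}

#' Bootstrap / permutation Kolmogorov-Smirnov test
#'
#' For small cohorts: the observed `D` is accompanied by the mean `D`
#' over `n_boot` within-group resamples with replacement
#' (`bootstrap_mean`), and an empirical p-value from label-permuted
#' resamples (the fraction with `D >= observed`).
#'
#' @inheritParams ks_two_sample
#' @param n_boot Number of resamples (default 1000).
#' @param seed Integer seed.
#' @return A `ks_result` with `bootstrap_mean`, `n_boot`, `seed`.
#' @export
ks_bootstrap <- function(x, y, n_boot = 1000L, seed = 1L) {
  base <- ks_two_sample(x, y)
  n1 <- base$n1; n2 <- base$n2
  pooled <- c(x, y)
  with_seed(seed, {
    d_boot <- numeric(n_boot)
    d_perm <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      xb <- x[sample.int(n1, n1, replace = TRUE)]
      yb <- y[sample.int(n2, n2, replace = TRUE)]
      d_boot[b] <- ks_stat_only(xb, yb)
      perm <- sample(pooled)
      d_perm[b] <- ks_stat_only(perm[seq_len(n1)], perm[-seq_len(n1)])
    }
  })
  structure(list(statistic = base$statistic,
                 p_value = mean(d_perm >= base$statistic),
                 n1 = n1, n2 = n2, bootstrap_mean = mean(d_boot),
                 n_boot = as.integer(n_boot), seed = seed),
            class = "ks_result")
}

ks_stat_only <- function(x, y) {
  # sorted two-pointer ECDF sup-difference
  all_v <- sort(c(x, y))
  cdf1 <- findInterval(all_v, sort(x)) / length(x)
  cdf2 <- findInterval(all_v, sort(y)) / length(y)
  max(abs(cdf1 - cdf2))
}

#' Gaussian kernel density summary
#'
#' Scott's-rule bandwidth (`sd * n^(-1/5)`), densities evaluated on an
#' even grid spanning the data plus/minus three bandwidths.
#'
#' @param values Numeric vector (non-constant).
#' @param grid_size Number of grid points (default 256).
#' @return data.frame with `x` (grid) and `density`.
#' @export
kde_summary <- function(values, grid_size = 256L) {
  if (length(values) < 2) stopf("need >= 2 values")
  bw <- sd(values) * length(values)^(-1 / 5)
  if (!is.finite(bw) || bw <= 0)
    stopf("zero bandwidth: input is constant")
  d <- density(values, bw = bw, from = min(values) - 3 * bw,
               to = max(values) + 3 * bw, n = grid_size)
  data.frame(x = d$x, density = d$y)
}

#' Per-feature KS report
#'
#' Class-wise two-sample KS statistics for a set of features, shaped
#' like a marker-stability table's distributional columns; switches to
#' the bootstrap variant when either class is smaller than
#' `small_n_cutoff`.
#'
#' @param mat An [expression_matrix()] (features x samples).
#' @param labels Outcome labels per sample.
#' @param features Feature ids to report (default: all rows).
#' @param alpha Significance cutoff on the p-value for the
#'   `significant` flag (default 0.1).
#' @param small_n_cutoff Class size below which the bootstrap variant is
#'   used (default 15).
#' @param n_boot,seed Passed to [ks_bootstrap()].
#' @return data.frame with `feature`, `statistic`, `p_value`,
#'   `significant`.
#' @export
ks_report <- function(mat, labels, features = rownames(mat), alpha = 0.1,
                      small_n_cutoff = 15L, n_boot = 1000L, seed = 1L) {
  pos <- labels == positive_class(labels)
  use_boot <- min(sum(pos), sum(!pos)) < small_n_cutoff
  rows <- lapply(features, function(f) {
    x <- as.numeric(mat[f, pos]); y <- as.numeric(mat[f, !pos])
    r <- if (use_boot) ks_bootstrap(x, y, n_boot, child_seed(seed, f))
         else ks_two_sample(x, y)
    data.frame(feature = f, statistic = r$statistic, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out
}
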