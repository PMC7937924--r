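#' Quantile normalization
#'
#' Forces every sample (column) to share the same value distribution:
#' the across-sample mean of order statistics.  Ties within a column
#' receive the mean of the reference values at their rank positions, so
#' the map is rank-based and idempotent.  Stands in for probe-level RMA
#' normalization, which needs raw array intensities this pipeline never
#' sees.
#'
#' @param mat An [expression_matrix()] with >= 2 samples.
#' @param warn_single Warn when called with a single sample (for which
#'   the operation is the identity).
#' @return A quantile-normalized [expression_matrix()].
#' @export
quantile_normalize <- function(mat, warn_single = TRUE) {
  if (ncol(mat) < 2) {
    if (warn_single) warnf("single sample: quantile normalization is identity")
    return(mat)
  }
  ref <- rowMeans(apply(unclass(mat), 2, sort))
  out <- apply(unclass(mat), 2, function(x) {
    res <- numeric(length(x))
    res[order(x)] <- ref
    # tied values share the mean of the reference values at their ranks
    ave(res, x, FUN = mean)
  })
  expression_matrix(out, rownames(mat), colnames(mat))
}

#' Estimate surrogate variables
#'
#' Residualizes each gene on the outcome design and takes the top-k
#' right singular vectors of the residual matrix as surrogate
#' components — latent covariates capturing unmodeled variation such as
#' processing batch.  Each component is tested against the declared
#' batch label by one-way ANOVA; in this pipeline the surrogates are a
#' diagnostic (reported, not regressed out) and [combat_adjust()] uses
#' the declared batch label.
#'
#' @param mat An [expression_matrix()].
#' @param design Outcome labels, one per sample.
#' @param k Number of components (k < n_samples - number of groups).
#' @param batch Optional batch labels for the ANOVA diagnostics.
#' @return A list of class `surrogate_variables` with `components`
#'   (samples x k, column-orthonormal), `d` (singular values), and
#'   `association` (per-component F statistic and p-value vs batch, when
#'   supplied).
#' @export
estimate_surrogates <- function(mat, design, k = 2L, batch = NULL) {
  if (k <= 0) stopf("k must be positive")
  design <- as.factor(design)
  n <- ncol(mat)
  if (k >= n - nlevels(design)) stopf("k must be < n_samples - rank(design)")
  X <- unclass(mat)
  # residualize each gene on the group means
  for (lev in levels(design)) {
    cols <- design == lev
    X[, cols] <- X[, cols, drop = FALSE] - rowMeans(X[, cols, drop = FALSE])
  }
  sv <- svd(X, nu = 0, nv = k)
  comp <- sv$v[, seq_len(k), drop = FALSE]
  rownames(comp) <- colnames(mat)
  colnames(comp) <- paste0("SV", seq_len(k))
  assoc <- NULL
  if (!is.null(batch)) {
    batch <- as.factor(batch)
    assoc <- do.call(rbind, lapply(seq_len(k), function(j) {
      a <- anova(lm(comp[, j] ~ batch))
      data.frame(component = paste0("SV", j), f = a$`F value`[1],
                 p = a$`Pr(>F)`[1])
    }))
  }
  structure(list(components = comp, d = sv$d[seq_len(k)],
                 association = assoc, k = k),
            class = "surrogate_variables")
}

#' Empirical-Bayes batch adjustment
#'
#' Parametric location/scale batch correction: per gene and batch,
#' additive and multiplicative batch parameters are estimated and shrunk
#' toward across-gene priors (normal for location, inverse-gamma for
#' scale, both moment-matched), while the outcome covariate is protected
#' in the standardization model.  After adjustment, batch-wise gene
#' means are approximately equal.
#'
#' @param mat An [expression_matrix()].
#' @param batch Batch labels, one per sample; every batch needs >= 2
#'   samples.
#' @param covariates Outcome labels protected during standardization
#'   (optional).
#' @return The adjusted [expression_matrix()].
#' @export
combat_adjust <- function(mat, batch, covariates = NULL) {
  batch <- as.factor(droplevels(as.factor(batch)))
  n <- ncol(mat)
  if (length(batch) != n) stopf("batch length must equal sample count")
  sizes <- table(batch)
  if (any(sizes < 2))
    stopf("singleton batch: %s", names(sizes)[sizes < 2][1])
  if (nlevels(batch) == 1) return(mat)

  # design: batch indicators (no intercept) + protected covariates
  if (!is.null(covariates)) {
    cov <- as.factor(covariates)
    if (nlevels(cov) > 1) {
      conf <- table(batch, cov)
      if (all(rowSums(conf > 0) == 1))
        stopf("outcome is fully confounded with batch; refusing to adjust")
      design <- stats::model.matrix(~ 0 + batch + cov)
    } else design <- stats::model.matrix(~ 0 + batch)
  } else design <- stats::model.matrix(~ 0 + batch)

  X <- unclass(mat)
  B <- t(solve(crossprod(design), crossprod(design, t(X)))) # genes x coef
  nb <- nlevels(batch)
  batch_effects <- B[, seq_len(nb), drop = FALSE]
  w <- as.numeric(sizes) / n
  grand <- as.numeric(batch_effects %*% w) # weighted grand mean per gene
  fitted_full <- B %*% t(design)
  resid <- X - fitted_full
  var_pooled <- rowSums(resid^2) / n
  var_pooled[var_pooled < 1e-12] <- 1e-12

  # non-batch part of the model (covariates), kept out of standardization
  extra <- if (ncol(B) > nb) {
    B[, -(seq_len(nb)), drop = FALSE] %*% t(design[, -(seq_len(nb)), drop = FALSE])
  } else 0
  Z <- (X - grand - extra) / sqrt(var_pooled)

  gamma_hat <- delta_hat <- matrix(NA_real_, nrow(X), nb)
  for (b in seq_len(nb)) {
    cols <- batch == levels(batch)[b]
    gamma_hat[, b] <- rowMeans(Z[, cols, drop = FALSE])
    delta_hat[, b] <- apply(Z[, cols, drop = FALSE], 1, var)
  }
  delta_hat[delta_hat < 1e-12] <- 1e-12

  gamma_star <- delta_star <- matrix(NA_real_, nrow(X), nb)
  for (b in seq_len(nb)) {
    nb_s <- as.numeric(sizes[b])
    g_bar <- mean(gamma_hat[, b]); t2 <- var(gamma_hat[, b])
    d_bar <- mean(delta_hat[, b]); s2 <- var(delta_hat[, b])
    # inverse-gamma prior, moment-matched
    lambda <- (2 * s2 + d_bar^2) / s2
    theta <- (d_bar * s2 + d_bar^3) / s2
    g_old <- gamma_hat[, b]; d_old <- delta_hat[, b]
    for (it in seq_len(100)) {
      g_new <- (nb_s * t2 * gamma_hat[, b] + d_old * g_bar) /
        (nb_s * t2 + d_old)
      cols <- batch == levels(batch)[b]
      sse <- rowSums((Z[, cols, drop = FALSE] - g_new)^2)
      d_new <- (theta + 0.5 * sse) / (nb_s / 2 + lambda - 1)
      if (max(abs(g_new - g_old), abs(d_new - d_old)) < 1e-6) {
        g_old <- g_new; d_old <- d_new; break
      }
      g_old <- g_new; d_old <- d_new
    }
    gamma_star[, b] <- g_old
    delta_star[, b] <- pmax(d_old, 1e-12)
  }

  out <- Z
  for (b in seq_len(nb)) {
    cols <- batch == levels(batch)[b]
    out[, cols] <- (Z[, cols, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta_star[, b])
  }
  out <- out * sqrt(var_pooled) + grand + extra
  # shrinkage toward across-gene prior means can drift the global location
  # by a tiny scalar; pin it so adjustment never moves the grand mean
  out <- out + (mean(X) - mean(out))
  expression_matrix(out, rownames(mat), colnames(mat))
}

#' Collapse probes to gene symbols
#'
#' Averages (unweighted mean) the expression of all probes mapping to
#' the same gene symbol, per sample.  A probe mapped to several genes
#' contributes to each; probes with missing or blank symbols, and probes
#' absent from the mapping, are dropped (counts reported via message).
#'
#' @param mat A probe-level [expression_matrix()].
#' @param mapping Two-column `data.frame` (`probe`, `symbol`), e.g. read
#'   from a 2-column CSV.
#' @return A gene-level [expression_matrix()], one row per distinct
#'   mapped symbol.
#' @export
collapse_probes <- function(mat, mapping) {
  stopifnot(all(c("probe", "symbol") %in% names(mapping)))
  mapping <- mapping[!is.na(mapping$symbol) & mapping$symbol != "", ]
  mapping <- mapping[mapping$probe %in% rownames(mat), ]
  if (nrow(mapping) == 0) stopf("no probes in common between matrix and mapping")
  n_unmapped <- sum(!rownames(mat) %in% mapping$probe)
  if (n_unmapped > 0)
    message(sprintf("collapse_probes: dropping %d unmapped probe(s)",
                    n_unmapped))
  expanded <- unclass(mat)[mapping$probe, , drop = FALSE]
  sums <- rowsum(expanded, group = mapping$symbol)
  counts <- as.vector(table(mapping$symbol)[rownames(sums)])
  expression_matrix(sums / counts, rownames(sums), colnames(mat))
}
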