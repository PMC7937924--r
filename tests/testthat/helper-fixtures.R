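# Shared fixtures, generated in code: no data files.

# tiny deterministic expression matrix
tiny_expr <- function(n_genes = 3, n_samples = 2, seed = 42) {
  withr::with_seed(seed, {
    expression_matrix(matrix(round(runif(n_genes * n_samples, 2, 12), 4),
                             n_genes, n_samples),
                      sprintf("g%d", seq_len(n_genes)),
                      sprintf("s%d", seq_len(n_samples)))
  })
}

# small synthetic cohort for fast pipeline-level tests
small_cohort <- function(seed = 7, n_samples = 60, n_genes = 150,
                         n_strong = 5, n_weak = 5, ...) {
  generate_cohort(synthetic_spec(n_samples = n_samples, n_genes = n_genes,
                                 n_strong = n_strong, n_weak = n_weak,
                                 seed = seed, ...))
}

# two-class feature matrix with separated Gaussian blobs
blob_data <- function(n_min = 15, n_maj = 45, d = 3, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_min * d), n_min, d) + sep,
               matrix(rnorm(n_maj * d), n_maj, d))
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = c(rep("complicated", n_min),
                      rep("uncomplicated", n_maj)))
  })
}

# brute-force AUROC oracle: explicit pair counting
auroc_oracle <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force two-sample KS oracle: double loop over evaluation points
ks_oracle <- function(x, y) {
  pts <- c(x, y)
  dmax <- 0
  for (t in pts) {
    d <- abs(mean(x <= t) - mean(y <= t))
    if (d > dmax) dmax <- d
  }
  dmax
}

# brute-force BH step-up oracle, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i) # rank of p[i]
    vals <- vapply(r:m, function(j) min(1, m * p[o[j]] / j), numeric(1))
    adj[i] <- min(vals)
  }
  adj
}
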