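#' Specification for a synthetic sepsis cohort
#'
#' Describes the statistical structure the generator emulates: a cohort
#' of ~228 peripheral-blood samples with ~23% complicated-course
#' prevalence, thousands of genes of which a small planted set carries
#' |log2FC| >= 1 effects, additive multi-batch shifts, a severity score
#' shifted upward in the positive class, and mortality nested inside the
#' positive class.
#'
#' @param n_samples Cohort size (default 228).
#' @param prevalence Positive-class fraction (default 52/228).
#' @param n_genes Number of genes (default 2000; desk-scale stand-in for
#'   the full ~20k array).
#' @param n_strong Genes with planted |delta| >= 1 (default 17).
#' @param n_weak Genes with planted 0.2 <= |delta| < 1 (default 50).
#' @param frac_up Fraction of planted effects that are upregulated
#'   (default 808/1269, the observed up/down mix).
#' @param sigma_range Per-gene noise SD range, sampled uniformly
#'   (default c(0.3, 0.8)).
#' @param n_batches Number of batches (default 2).
#' @param batch_sd SD of per-gene additive batch shifts (default 0.5).
#' @param severity_effect Mean severity-score shift in the positive
#'   class, in SD units (default 1.2).
#' @param mortality_rate_in_positive Death rate within the complicated
#'   group (default 28/52).
#' @param exact_prevalence Force exactly `round(n * prevalence)`
#'   positives rather than binomial draws (default TRUE).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 228L, prevalence = 52 / 228,
                           n_genes = 2000L, n_strong = 17L, n_weak = 50L,
                           frac_up = 808 / 1269,
                           sigma_range = c(0.3, 0.8),
                           n_batches = 2L, batch_sd = 0.5,
                           severity_effect = 1.2,
                           mortality_rate_in_positive = 28 / 52,
                           exact_prevalence = TRUE, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stopf("prevalence must be in (0,1)")
  if (n_strong + n_weak > n_genes)
    stopf("n_strong + n_weak must not exceed n_genes")
  spec <- list(n_samples = as.integer(n_samples), prevalence = prevalence,
               n_genes = as.integer(n_genes), n_strong = as.integer(n_strong),
               n_weak = as.integer(n_weak), frac_up = frac_up,
               sigma_range = sigma_range, n_batches = as.integer(n_batches),
               batch_sd = batch_sd, severity_effect = severity_effect,
               mortality_rate_in_positive = mortality_rate_in_positive,
               exact_prevalence = isTRUE(exact_prevalence),
               seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

# Planted effect sizes: strong |delta| ~ U[1.25, 2]; weak |delta| ~
# U[0.2, 0.5].  The strong class sits clear of the |log2FC| >= 1 filter
# because the list it emulates was itself selected on observed fold
# change (planting at the boundary would make recovery a coin flip
# against sampling noise of ~0.09 log2 units); the weak class is bounded
# well below the cutoff because observed DEG effect-size distributions
# concentrate at small fold changes (a handful of genes at |log2FC| >= 1
# among >1000 DEGs).
draw_deltas <- function(spec) {
  n_eff <- spec$n_strong + spec$n_weak
  if (n_eff == 0) return(numeric(0))
  mag <- c(runif(spec$n_strong, 1.25, 2),
           if (spec$n_weak > 0) runif(spec$n_weak, 0.2, 0.5) else numeric(0))
  sign <- ifelse(runif(n_eff) < spec$frac_up, 1, -1)
  mag * sign
}

#' Generate a synthetic derivation cohort
#'
#' Value model for gene g, sample i:
#' `x_gi = b_g + gamma_(batch(i),g) + delta_g * 1[complicated_i] + eps_gi`
#' with `eps ~ N(0, sigma_g^2)`, baseline `b_g ~ N(7, 1.5)` on the log2
#' scale, and per-gene batch shifts `gamma ~ N(0, batch_sd^2)`.  The
#' severity score is `N(0,1) + severity_effect * 1[complicated]`;
#' mortality is drawn only within the positive class.  Fully
#' reproducible from the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @param n_folds Used only to warn when the prevalence would leave a CV
#'   fold with fewer than 2 positives.
#' @return A list with `expr` ([expression_matrix()]), `pheno`
#'   (phenotype `data.frame`), and `truth` (planted gene ids, deltas and
#'   batch shift matrix).
#' @export
generate_cohort <- function(spec, n_folds = 5L) {
  with_seed(spec$seed, {
    n <- spec$n_samples
    p <- spec$n_genes
    n_pos <- if (spec$exact_prevalence) {
      as.integer(round(n * spec$prevalence))
    } else rbinom(1, n, spec$prevalence)
    if (n_pos / n_folds < 2)
      warnf("prevalence yields <2 positives per fold at n_folds=%d", n_folds)
    outcome <- rep("uncomplicated", n)
    outcome[sample.int(n, n_pos)] <- "complicated"
    batch <- paste0("batch", sample(rep_len(seq_len(spec$n_batches), n)))

    gene_ids <- sprintf("G%04d", seq_len(p))
    sample_ids <- sprintf("S%03d", seq_len(n))
    b <- rnorm(p, 7, 1.5)
    sigma <- runif(p, spec$sigma_range[1], spec$sigma_range[2])
    delta <- numeric(p)
    n_eff <- spec$n_strong + spec$n_weak
    planted_idx <- if (n_eff > 0) sample.int(p, n_eff) else integer(0)
    delta[planted_idx] <- draw_deltas(spec)
    gamma <- matrix(rnorm(p * spec$n_batches, 0, spec$batch_sd),
                    p, spec$n_batches,
                    dimnames = list(gene_ids,
                                    paste0("batch", seq_len(spec$n_batches))))
    if (spec$n_batches == 1 || spec$batch_sd == 0) gamma[] <- 0

    pos <- outcome == "complicated"
    batch_i <- match(batch, colnames(gamma))
    X <- b + gamma[, batch_i, drop = FALSE] +
      outer(delta, as.numeric(pos)) +
      matrix(rnorm(p * n), p, n) * sigma

    severity <- rnorm(n) + spec$severity_effect * pos
    mortality <- rep(FALSE, n)
    mortality[pos] <- runif(sum(pos)) < spec$mortality_rate_in_positive
    sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.61, 0.39))
    age <- pmax(0.1, rnorm(n, 3.8, 3.4))

    pheno <- data.frame(sample_id = sample_ids, outcome = outcome,
                        batch = batch, severity_score = severity,
                        mortality = mortality, age = round(age, 2),
                        sex = sex, stringsAsFactors = FALSE)
    truth <- list(
      planted_genes = gene_ids[planted_idx],
      strong_genes = gene_ids[planted_idx[abs(delta[planted_idx]) >= 1]],
      weak_genes = gene_ids[planted_idx[abs(delta[planted_idx]) < 1]],
      delta = setNames(delta[planted_idx], gene_ids[planted_idx]),
      batch_shifts = gamma, baseline = setNames(b, gene_ids),
      sigma = setNames(sigma, gene_ids))
    list(expr = expression_matrix(X, gene_ids, sample_ids),
         pheno = pheno, truth = truth)
  })
}

#' Generate an attenuated external-validation cohort
#'
#' Shares the derivation cohort's planted gene identities but keeps only
#' `ceiling(retained_fraction * n_strong)` of the strong planted
#' effects, each scaled by `attenuation` (weak derivation effects carry
#' no signal here) — emulating that markers discovered in one population
#' may carry weaker (or no) signal in another.  Sample ids are distinct
#' from any derivation cohort.
#'
#' @param spec A [synthetic_spec()] describing the validation cohort's
#'   size/noise structure.
#' @param truth The `truth` record from [generate_cohort()] whose gene
#'   identities are shared.
#' @param attenuation Effect-size multiplier in `[0, 1]`.
#' @param retained_fraction Fraction of planted genes keeping an effect.
#' @param seed Integer seed (defaults to `spec$seed + 1`).
#' @param label_name Outcome column name in the returned phenotype
#'   (e.g. `"mortality"` for cohorts labeled by death); the standard
#'   `outcome` column is always present.
#' @return As [generate_cohort()].
#' @export
generate_validation_cohort <- function(spec, truth, attenuation = 1,
                                       retained_fraction = 1,
                                       seed = spec$seed + 1L,
                                       label_name = NULL) {
  stopifnot(attenuation >= 0, attenuation <= 1,
            retained_fraction >= 0, retained_fraction <= 1)
  planted <- names(truth$delta)
  eligible <- truth$strong_genes
  n_keep <- as.integer(ceiling(retained_fraction * length(eligible)))
  vspec <- spec
  vspec$seed <- as.integer(seed)
  with_seed(vspec$seed, {
    keep <- if (n_keep > 0) {
      eligible[sample.int(length(eligible), n_keep)]
    } else character(0)
    n <- vspec$n_samples
    p <- vspec$n_genes
    gene_ids <- names(truth$baseline)
    if (length(gene_ids) != p)
      stopf("validation spec n_genes must match derivation truth")
    n_pos <- as.integer(round(n * vspec$prevalence))
    outcome <- rep("uncomplicated", n)
    outcome[sample.int(n, n_pos)] <- "complicated"
    batch <- paste0("batch", sample(rep_len(seq_len(vspec$n_batches), n)))
    sample_ids <- sprintf("V%03d", seq_len(n))

    delta <- setNames(numeric(p), gene_ids)
    delta[keep] <- truth$delta[keep] * attenuation
    sigma <- truth$sigma
    gamma <- matrix(rnorm(p * vspec$n_batches, 0, vspec$batch_sd), p,
                    vspec$n_batches,
                    dimnames = list(gene_ids,
                                    paste0("batch", seq_len(vspec$n_batches))))
    if (vspec$n_batches == 1 || vspec$batch_sd == 0) gamma[] <- 0
    pos <- outcome == "complicated"
    X <- truth$baseline + gamma[, match(batch, colnames(gamma)), drop = FALSE] +
      outer(delta, as.numeric(pos)) + matrix(rnorm(p * n), p, n) * sigma

    severity <- rnorm(n) + vspec$severity_effect * pos
    mortality <- rep(FALSE, n)
    mortality[pos] <- runif(sum(pos)) < vspec$mortality_rate_in_positive
    pheno <- data.frame(sample_id = sample_ids, outcome = outcome,
                        batch = batch, severity_score = severity,
                        mortality = mortality, stringsAsFactors = FALSE)
    if (!is.null(label_name)) pheno[[label_name]] <- outcome == "complicated"
    vtruth <- list(planted_genes = planted, retained_genes = keep,
                   delta = delta[delta != 0], batch_shifts = gamma)
    list(expr = expression_matrix(X, gene_ids, sample_ids),
         pheno = pheno, truth = vtruth)
  })
}
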