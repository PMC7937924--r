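#' Moderated two-group t-test
#'
#' Per-gene two-group comparison (complicated minus uncomplicated) with
#' empirical-Bayes variance moderation: the residual variances `s_g^2`
#' (df `d`) are shrunk toward a prior `(d0, s0^2)` fitted by moment
#' matching on `log s_g^2`, giving posterior variances
#' `s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d)` and moderated statistics
#' `t_g = log2fc_g / (s~_g sqrt(1/n1 + 1/n0))` on `d0 + d` degrees of
#' freedom.
#'
#' @param mat An [expression_matrix()] (log2 scale).
#' @param labels Outcome labels (`"complicated"`/`"uncomplicated"`), one
#'   per sample; >= 2 samples per class.
#' @param prior_df Override the fitted prior df `d0` (`0` turns
#'   moderation off, recovering the ordinary pooled t-test; `NULL`
#'   fits it; capped at 1e6).
#' @return A `data.frame` (class `dge_table`) with one row per gene:
#'   `gene`, `log2fc`, `avg_expr`, `t_mod`, `df_total`, `p`,
#'   `zero_var` flag; see [bh_adjust()] / [select_degs()] for the
#'   adjusted columns.
#' @export
moderated_t_test <- function(mat, labels, prior_df = NULL) {
  pos <- labels == "complicated"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2 || n0 < 2) stopf("need >= 2 samples per class")
  X <- unclass(mat)
  m1 <- rowMeans(X[, pos, drop = FALSE])
  m0 <- rowMeans(X[, !pos, drop = FALSE])
  log2fc <- m1 - m0
  d <- n1 + n0 - 2
  ss <- rowSums((X[, pos, drop = FALSE] - m1)^2) +
    rowSums((X[, !pos, drop = FALSE] - m0)^2)
  s2 <- ss / d
  zero_var <- s2 <= 0

  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2[!zero_var], d)
    d0 <- fit$d0; s02 <- fit$s02
  } else if (prior_df == 0) {
    d0 <- 0; s02 <- 0
  } else {
    d0 <- min(prior_df, 1e6)
    s02 <- if (any(!zero_var)) median(s2[!zero_var]) else 1
  }

  s2_post <- if (d0 > 0) (d0 * s02 + d * s2) / (d0 + d) else s2
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  t_mod <- ifelse(se > 0, log2fc / se, 0)
  df_total <- d0 + d
  p <- 2 * pt(-abs(t_mod), df = df_total)
  # genes with no variance anywhere and no mean difference are uninformative
  flat <- zero_var & log2fc == 0
  t_mod[flat] <- 0; p[flat] <- 1

  structure(data.frame(gene = rownames(mat), log2fc = log2fc,
                       avg_expr = rowMeans(X), t_mod = t_mod,
                       df_total = df_total, p = p, zero_var = zero_var,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("dge_table", "data.frame"),
            prior = list(d0 = d0, s02 = s02, n1 = n1, n0 = n0))
}

# Empirical-Bayes prior for gene variances: moment matching of
# z = log(s^2) against the scaled-F model, inverting the trigamma
# relation Var(z) = trigamma(d/2) + trigamma(d0/2) by Newton steps.
fit_variance_prior <- function(s2, d) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- var(e)
  rhs <- evar - trigamma(d / 2)
  if (!is.finite(rhs) || rhs <= 1e-8) {
    d0 <- 1e6 # variances essentially exchangeable: near-complete shrinkage
  } else {
    # solve trigamma(d0/2) = rhs; trigamma is decreasing and convex
    x <- 0.5 + 1 / rhs
    for (i in 1:60) {
      delta <- trigamma(x) * (1 - trigamma(x) / rhs) / psigamma(x, 2)
      x <- x + delta
      if (abs(delta) < 1e-10 * x) break
    }
    d0 <- min(2 * x, 1e6)
  }
  s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj(i) = min over j with rank >= rank(i) of min(1, m p(j) / j)`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, elementwise >= input, <= 1, monotone
#'   nondecreasing in p-rank.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Flag and rank differentially expressed genes
#'
#' Adds BH-adjusted p-values and DEG flags to a [moderated_t_test()]
#' table and extracts the gene lists: all DEGs (`p_adj < fdr_cutoff`),
#' top DEGs (additionally `|log2fc| >= lfc_cutoff`), and the up/down
#' partition.  Ordering is deterministic: p, then |log2fc| descending,
#' then gene id.
#'
#' @param table A `dge_table` from [moderated_t_test()].
#' @param fdr_cutoff BH-FDR cutoff (default 0.1).
#' @param lfc_cutoff Absolute log2 fold-change cutoff for top DEGs
#'   (default 1).
#' @return A list with the annotated `table` plus character vectors
#'   `degs`, `top_degs`, `up`, `down`.
#' @export
select_degs <- function(table, fdr_cutoff = 0.1, lfc_cutoff = 1.0) {
  tab <- as.data.frame(table)
  tab$p_adj <- bh_adjust(tab$p)
  tab$is_deg <- tab$p_adj < fdr_cutoff
  tab$is_top_deg <- tab$is_deg & abs(tab$log2fc) >= lfc_cutoff
  ord <- order(tab$p, -abs(tab$log2fc), tab$gene)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  # volcano-style category labels for downstream table exports
  tab$category <- ifelse(tab$is_top_deg, "lfc+sig",
                         ifelse(tab$is_deg, "sig-only", "ns"))
  list(table = tab,
       degs = tab$gene[tab$is_deg],
       top_degs = tab$gene[tab$is_top_deg],
       up = tab$gene[tab$is_deg & tab$log2fc > 0],
       down = tab$gene[tab$is_deg & tab$log2fc < 0])
}

#' Write a DGE table as TSV
#'
#' Fixed column order: gene, log2fc, avg_expr, t_mod, df_total, p,
#' p_adj, is_deg, is_top_deg, category.
#'
#' @param deg_result Result of [select_degs()].
#' @param path Output path.
#' @export
write_dge_table <- function(deg_result, path) {
  cols <- c("gene", "log2fc", "avg_expr", "t_mod", "df_total", "p",
            "p_adj", "is_deg", "is_top_deg", "category")
  tab <- deg_result$table[, cols]
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
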