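test_that("quantile normalization matches the by-hand small case", {
  mat <- expression_matrix(cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6)),
                           c("g1", "g2", "g3"), c("s1", "s2"))
  qn <- quantile_normalize(mat)
  expect_equal(unname(unclass(qn)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(qn)[, 2]), c(2.5, 3.5, 4.5))
})

test_that("quantile normalization is rank-based and idempotent", {
  withr::with_seed(8, {
    m <- matrix(rnorm(50 * 6, 7, 2), 50, 6)
    mat <- expression_matrix(m, sprintf("g%d", 1:50), sprintf("s%d", 1:6))
  })
  qn <- quantile_normalize(mat)
  # row order respected: output ranks equal input ranks per column
  for (j in 1:6) expect_equal(rank(qn[, j]), rank(mat[, j]))
  qn2 <- quantile_normalize(qn)
  expect_equal(unclass(qn2), unclass(qn), tolerance = 1e-9)
  # identical columns unchanged
  same <- expression_matrix(cbind(a = c(1, 5, 9), b = c(1, 5, 9)),
                            c("g1", "g2", "g3"), c("a", "b"))
  expect_equal(unclass(quantile_normalize(same)), unclass(same),
               ignore_attr = TRUE)
})

test_that("quantile normalization ties get mean reference values", {
  mat <- expression_matrix(cbind(s1 = c(2, 2, 10), s2 = c(1, 5, 9)),
                           c("g1", "g2", "g3"), c("s1", "s2"))
  qn <- quantile_normalize(mat)
  ref <- rowMeans(cbind(sort(mat[, 1]), sort(mat[, 2])))
  expect_equal(unname(qn[c("g1", "g2"), "s1"]),
               rep(mean(ref[1:2]), 2)) # tied pair shares mean of ref[1:2]
  expect_equal(unname(qn["g3", "s1"]), unname(ref[3]))
})

test_that("quantile normalization agrees with the limma reference", {
  skip_if_not_installed("limma")
  withr::with_seed(21, m <- matrix(rnorm(200 * 8, 7, 2), 200, 8))
  mat <- expression_matrix(m, sprintf("g%d", 1:200), sprintf("s%d", 1:8))
  ours <- unclass(quantile_normalize(mat))
  theirs <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("single-sample input warns and returns identity", {
  mat <- tiny_expr(4, 1)
  expect_warning(out <- quantile_normalize(mat), "single sample")
  expect_equal(unclass(out), unclass(mat))
})

test_that("surrogate components are orthonormal and detect planted batches", {
  co <- generate_cohort(synthetic_spec(n_samples = 80, n_genes = 300,
                                       n_strong = 3, n_weak = 0,
                                       batch_sd = 0.5, seed = 13))
  sv <- estimate_surrogates(co$expr, co$pheno$outcome, k = 3,
                            batch = co$pheno$batch)
  expect_equal(crossprod(sv$components), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(sv$association$p[1], 0.01)
  expect_error(estimate_surrogates(co$expr, co$pheno$outcome, k = 0), "k")
  expect_error(estimate_surrogates(co$expr, co$pheno$outcome, k = 79),
               "rank")
})

test_that("residualized matrix has at most rank-r spectrum", {
  # two groups of identical columns -> residual matrix is exactly zero
  m <- cbind(a = c(1, 2), b = c(1, 2), c = c(5, 3), d = c(5, 3))
  mat <- expression_matrix(m, c("g1", "g2"), letters[1:4])
  sv <- estimate_surrogates(mat, c("complicated", "complicated",
                                   "uncomplicated", "uncomplicated"), k = 1)
  expect_equal(sv$d[1], 0, tolerance = 1e-10)
})

test_that("batch adjustment removes a planted additive shift", {
  # shift-only world: planted outcome effects would confound the naive
  # between-batch gene-mean gap whenever batches differ in case fraction
  co <- generate_cohort(synthetic_spec(seed = 17, n_samples = 120,
                                       n_genes = 400, n_strong = 0,
                                       n_weak = 0, batch_sd = 0.5))
  adj <- combat_adjust(co$expr, co$pheno$batch, co$pheno$outcome)
  b <- co$pheno$batch
  gap <- abs(rowMeans(adj[, b == "batch1"]) - rowMeans(adj[, b == "batch2"]))
  expect_gte(mean(gap < 0.05), 0.95)
  # global mean preserved (balanced batches)
  expect_equal(mean(adj), mean(co$expr), tolerance = 1e-6)
})

test_that("batch adjustment handles degenerate designs explicitly", {
  mat <- tiny_expr(10, 6, seed = 2)
  # single batch: identity
  expect_equal(unclass(combat_adjust(mat, rep("b1", 6))), unclass(mat))
  # singleton batch: error naming it
  expect_error(combat_adjust(mat, c("b1", "b1", "b1", "b1", "b1", "b2")),
               "singleton batch: b2")
  # full confounding outcome ~ batch: refuse
  expect_error(
    combat_adjust(mat, rep(c("b1", "b2"), each = 3),
                  rep(c("complicated", "uncomplicated"), each = 3)),
    "confounded")
})

test_that("probe collapse averages, re-keys, and honors multi-mapping", {
  mat <- expression_matrix(rbind(p1 = c(2, 4), p2 = c(4, 6), p3 = c(1, 1)),
                           c("p1", "p2", "p3"), c("s1", "s2"))
  mapping <- data.frame(probe = c("p1", "p2"), symbol = c("geneA", "geneA"))
  out <- suppressMessages(collapse_probes(mat, mapping))
  expect_equal(unname(out["geneA", ]), c(3, 5), ignore_attr = TRUE)
  expect_equal(nrow(out), 1L)

  # 1:1 mapping renames only
  m2 <- data.frame(probe = c("p1", "p2", "p3"), symbol = c("a", "b", "c"))
  out2 <- collapse_probes(mat, m2)
  expect_equal(unname(unclass(out2)[order(rownames(out2)), ]),
               unname(unclass(mat)), ignore_attr = TRUE)

  # multi-mapped probe contributes to both genes
  m3 <- data.frame(probe = c("p1", "p1", "p2"),
                   symbol = c("gA", "gB", "gB"))
  out3 <- suppressMessages(collapse_probes(mat, m3))
  expect_equal(unname(out3["gA", ]), c(2, 4), ignore_attr = TRUE)
  expect_equal(unname(out3["gB", ]), c(3, 5), ignore_attr = TRUE)
  expect_equal(nrow(out3), length(unique(m3$symbol)))

  expect_error(collapse_probes(mat, data.frame(probe = "zz", symbol = "q")),
               "common")
})
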