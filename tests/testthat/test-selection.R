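test_that("RF importance puts a determinative feature first", {
  wins <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      X <- matrix(rnorm(60 * 10), 60, 10)
      colnames(X) <- sprintf("f%02d", 1:10)
      y <- rep(c("complicated", "uncomplicated"), each = 30)
      X[, 1] <- ifelse(y == "complicated", 1, -1) # perfectly determined
    })
    sel <- rf_importance_select(X, y, n_trees = 100, seed = s)
    if (sel[1] == "f01") wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("RF importance of a constant feature is zero and runs are seeded", {
  b <- blob_data(n_min = 20, n_maj = 20, d = 4, seed = 3)
  b$X[, 4] <- 1
  m <- fit_classifier("rf", b$X, b$y, list(n_trees = 50), seed = 5)
  expect_equal(unname(feature_importance(m)["f4"]), 0)
  s1 <- rf_importance_select(b$X[, 1:3], b$y, n_trees = 50, seed = 9)
  s2 <- rf_importance_select(b$X[, 1:3], b$y, n_trees = 50, seed = 9)
  expect_identical(s1, s2)
})

test_that("LASSO selection is sparse under the null and drops duplicates", {
  nulls <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      X <- matrix(rnorm(80 * 30), 80, 30)
      colnames(X) <- sprintf("f%02d", 1:30)
      y <- rep(c("complicated", "uncomplicated"), each = 40)
    })
    length(lasso_select(X, y, seed = s))
  }, numeric(1))
  expect_gte(mean(nulls <= 1), 0.9)

  # duplicated informative column: at most one survives a strong penalty
  withr::with_seed(4, {
    X <- matrix(rnorm(60 * 5), 60, 5)
    y <- rep(c("complicated", "uncomplicated"), each = 30)
    X[, 1] <- ifelse(y == "complicated", 1, 0) + rnorm(60, 0, 0.1)
    X[, 2] <- X[, 1]
    colnames(X) <- sprintf("f%d", 1:5)
  })
  m <- fit_classifier("lasso", X, y, params = list(lambda = 0.1), seed = 1)
  co <- feature_importance(m)
  expect_lte(sum(co[c("f1", "f2")] > 1e-8), 1)
  # penalty -> infinity: empty
  m2 <- fit_classifier("lasso", X, y, params = list(lambda = 1e6), seed = 1)
  expect_equal(sum(feature_importance(m2) > 0), 0)
})

test_that("mRMR never picks an exact copy while alternatives remain", {
  withr::with_seed(6, {
    X <- cbind(a = rnorm(50), b = 0, c = rnorm(50), d = rnorm(50))
    y <- rep(c("complicated", "uncomplicated"), each = 25)
    X[, "a"] <- X[, "a"] + (y == "complicated") * 3
    X[, "b"] <- X[, "a"] # exact duplicate of the best feature
    X[, "c"] <- X[, "c"] + (y == "complicated") * 1
    X[, "d"] <- X[, "d"] + (y == "complicated") * 0.5
  })
  sel <- mrmr_select(X, y, 3)
  expect_equal(sel[1], "a") # k = 1 would be argmax F
  expect_false("b" %in% sel)
  expect_error(mrmr_select(X, y, 9), "<=")
})

test_that("mRMR breaks exact ties by feature name", {
  # two orthogonal, equally relevant features by construction
  y <- rep(c("complicated", "uncomplicated"), each = 10)
  base <- c(rep(1, 10), rep(-1, 10))
  X <- cbind(zz = base, aa = base * c(1, -1))
  X[, "aa"] <- c(rep(1, 10), rep(-1, 10)) # identical relevance to zz
  X2 <- cbind(bb = X[, "zz"], aa = X[, "aa"])
  sel <- mrmr_select(X2, y, 1)
  expect_equal(sel, "aa")
})

test_that("feature pooling is a deterministic, order-insensitive union", {
  p1 <- pool_features(list(rf = c("g3", "g1"), lasso = c("g4", "g2"),
                           mrmr = c("g5")),
                      degs = c("g6", "g2"), clinical = "sev")
  expect_setequal(p1$pooled, c("sev", "g1", "g2", "g3", "g4", "g5", "g6"))
  expect_equal(p1$pooled[1], "sev") # clinical first
  p2 <- pool_features(list(rf = c("g1", "g3"), lasso = c("g2", "g4"),
                           mrmr = c("g5")),
                      degs = c("g2", "g6"), clinical = "sev")
  expect_identical(p1$pooled, p2$pooled)
  # fully overlapping lists collapse; empty methods leave degs + clinical
  p3 <- pool_features(list(rf = c("a"), lasso = c("a"), mrmr = c("a")),
                      degs = character(0), clinical = character(0))
  expect_identical(p3$pooled, "a")
  p4 <- pool_features(list(rf = character(0)), degs = c("d1"),
                      clinical = c("sev"))
  expect_identical(p4$pooled, c("sev", "d1"))
  # disjoint sizes 3/4/5 + 2 degs + 1 clinical = 15
  p5 <- pool_features(list(rf = paste0("r", 1:3), lasso = paste0("l", 1:4),
                           mrmr = paste0("m", 1:5)),
                      degs = paste0("d", 1:2), clinical = "sev")
  expect_length(p5$pooled, 15)
})

test_that("RFE returns exactly target features, identity when pool == target", {
  co <- small_cohort(seed = 29, n_samples = 70, n_genes = 120,
                     n_strong = 6, n_weak = 2)
  X <- t(unclass(co$expr)); y <- co$pheno$outcome
  pool <- pool_features(list(rf = colnames(X)[1:30]),
                        degs = co$truth$strong_genes,
                        clinical = character(0))
  out <- rfe(X, y, pool, target = 10, seed = 3)
  expect_length(out, 10)
  expect_true(all(out %in% pool$pooled))
  expect_identical(rfe(X, y, pool$pooled[1:10], target = 10, seed = 1),
                   pool$pooled[1:10])
  expect_error(rfe(X, y, pool, target = 40), "target")
})

test_that("RFE keeps planted strong genes and protected clinical features", {
  hits <- 0
  for (s in 1:5) {
    co <- small_cohort(seed = 100 + s, n_samples = 80, n_genes = 150,
                       n_strong = 5, n_weak = 5)
    X <- cbind(t(unclass(co$expr)),
               severity_score = co$pheno$severity_score)
    y <- co$pheno$outcome
    pool <- pool_features(list(rf = rownames(co$expr)[1:60]),
                          degs = co$truth$strong_genes,
                          clinical = "severity_score")
    out <- rfe(X, y, pool, target = 8, seed = s)
    expect_true("severity_score" %in% out)
    if (all(co$truth$strong_genes %in% out)) hits <- hits + 1
  }
  expect_gte(hits, 4) # >= 90% of seeds at scale; allow one miss in five
})

test_that("selectors only ever return subsets of their input features", {
  b <- blob_data(n_min = 15, n_maj = 30, d = 6, seed = 44)
  feats <- colnames(b$X)
  expect_true(all(rf_importance_select(b$X, b$y, 50, seed = 1) %in% feats))
  expect_true(all(lasso_select(b$X, b$y, seed = 1) %in% feats))
  expect_true(all(mrmr_select(b$X, b$y, 4) %in% feats))
})
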