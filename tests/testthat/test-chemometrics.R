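# NIPALS PCA, PLS-DA, OPLS-DA, VIP, Q2 and permutation validation.

test_that("NIPALS PCA matches the full singular value decomposition", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(rnorm(24), 6, 4)
    Xc <- scale(X, scale = FALSE)
    m <- fit_pca(Xc, n_components = 4, center = FALSE)
    sv <- svd(Xc)
    expect_lt(max(abs(m$r2x - sv$d[1:4]^2 / sum(sv$d^2))), 1e-8)
    # loadings orthonormal
    G <- crossprod(m$loadings)
    expect_lt(max(abs(G - diag(4))), 1e-8)
    # full reconstruction
    expect_lt(max(abs(m$scores %*% t(m$loadings) - Xc)), 1e-8)
  }
})

test_that("PCA handles rank-1 data and duplicated samples", {
  m <- fit_pca(rbind(c(1, 0), c(-1, 0)), n_components = 1, center = FALSE)
  expect_equal(m$r2x, 1)
  set.seed(2)
  X <- matrix(rnorm(30), 6, 5)
  m1 <- fit_pca(X, 2)
  m2 <- fit_pca(rbind(X, X), 2)
  expect_equal(m1$loadings, m2$loadings, tolerance = 1e-8)
  expect_error(fit_pca(X, 10), "n_components")
  expect_error(fit_pca(X[1, , drop = FALSE], 1), "2 samples")
})

test_that("PCA contributions are normalized squared loadings", {
  # rank-1 data with loading direction (0.6, 0.8)
  t <- c(-2, -1, 1, 2)
  X <- outer(t, c(0.6, 0.8))
  m <- fit_pca(X, 1, center = FALSE)
  contrib <- pca_contributions(m, 1)
  expect_equal(sort(contrib$contribution), c(0.36, 0.64), tolerance = 1e-10)
  expect_equal(sum(contrib$contribution), 1)
  # one-hot loading
  X2 <- cbind(c(-1, 0, 1), 0)
  m2 <- fit_pca(X2, 1, center = FALSE)
  c2 <- pca_contributions(m2, 1)
  expect_equal(c2$contribution[1], 1)
  # top_k = all features returns a permutation
  expect_setequal(pca_contributions(m, 1, top_k = 2)$feature, m$features)
  expect_error(pca_contributions(m, 3), "component")
})

test_that("PLS-DA recovers a pure single-feature response", {
  y <- factor(rep(c("control", "case"), each = 4),
              levels = c("control", "case"))
  yc <- as.numeric(y) - 1.5
  set.seed(7)
  noise <- matrix(rnorm(24), 8, 3)
  noise <- noise - outer(yc, colSums(noise * yc) / sum(yc^2))  # orthogonalize
  X <- cbind(sig = yc, noise)
  m <- fit_plsda(X, y, n_components = 1)
  expect_equal(abs(m$weights[1, 1]), 1, tolerance = 1e-8)
  expect_lt(max(abs(m$weights[-1, 1])), 1e-8)
  expect_equal(m$r2y, 1, tolerance = 1e-8)
})

test_that("PLS-DA rejects a single-class response", {
  set.seed(1)
  X <- matrix(rnorm(20), 5, 4)
  expect_error(fit_plsda(X, rep("a", 5), 1), "two classes")
})

test_that("training predictions reproduce the fitted response", {
  d <- random_two_class(6, 5, seed = 3)
  m <- fit_plsda(d$X, d$y, n_components = 2)
  pr <- predict(m, d$X)
  expect_lt(max(abs(pr$y_score - fitted(m))), 1e-10)
  expect_lt(max(abs(pr$scores - m$scores)), 1e-10)
})

test_that("full-rank PLS-DA reproduces the least-squares fit", {
  d <- random_two_class(4, 3, seed = 5)
  m <- fit_plsda(d$X, d$y, n_components = 3)
  y01 <- as.numeric(d$y) - 1
  ls <- lm.fit(cbind(1, d$X), y01)
  expect_lt(max(abs(fitted(m) - ls$fitted.values)), 1e-6)
})

test_that("OPLS-DA reduces to PLS-DA when no orthogonal structure exists", {
  y <- factor(rep(c("control", "case"), each = 5),
              levels = c("control", "case"))
  yc <- as.numeric(y) - 1.5
  w <- c(0.5, -0.3, 0.8, 0.1)
  X <- outer(yc, w)   # all X-variation is predictive
  mo <- fit_oplsda(X, y, n_orthogonal = 1)
  mp <- fit_plsda(X, y, n_components = 1)
  expect_lt(sum(mo$scores_orth^2) / sum(scale(X, scale = FALSE)^2), 1e-8)
  expect_equal(mo$r2y, mp$r2y, tolerance = 1e-8)
  expect_lt(max(abs(mo$scores[, 1] - mp$scores[, 1])), 1e-8)
})

test_that("OPLS-DA predictive scores are orthogonal to orthogonal scores", {
  for (seed in 1:5) {
    d <- random_two_class(8, 6, seed = seed)
    m <- fit_oplsda(d$X, d$y, n_orthogonal = 2)
    for (h in 1:2)
      expect_lt(abs(cor(m$scores[, 1], m$scores_orth[, h])), 1e-8)
  }
})

test_that("OPLS-DA(1+h) explains the response like PLS-DA(1+h)", {
  d <- random_two_class(6, 5, seed = 9)
  mo <- fit_oplsda(d$X, d$y, n_orthogonal = 1)
  mp <- fit_plsda(d$X, d$y, n_components = 2)
  expect_equal(mo$r2y, mp$r2y, tolerance = 1e-6)
})

test_that("VIP matches its closed form and normalization", {
  # w = (1, 0): second feature exactly orthogonal to the response
  y <- factor(rep(c("control", "case"), each = 3),
              levels = c("control", "case"))
  yc <- as.numeric(y) - 1.5
  x2 <- c(1, -1, 0, 0, 1, -1)
  x2 <- x2 - yc * sum(x2 * yc) / sum(yc^2)
  X <- cbind(a = yc, b = x2)
  m <- fit_plsda(X, y, n_components = 1)
  v <- vip(m)
  expect_equal(unname(v), c(sqrt(2), 0), tolerance = 1e-8)

  for (seed in 1:5) {
    d <- random_two_class(6, 7, seed = seed)
    expect_equal(mean(vip(fit_plsda(d$X, d$y, 2))^2), 1, tolerance = 1e-8)
    expect_equal(mean(vip(fit_oplsda(d$X, d$y, 1))^2), 1, tolerance = 1e-8)
  }
  expect_error(vip(fit_pca(random_two_class(4, 3, 1)$X, 2)), "PLS")
})

test_that("Q2 is 1 for a perfectly predictive feature and below R2Y otherwise", {
  y <- factor(rep(c("control", "case"), each = 10),
              levels = c("control", "case"))
  X <- cbind(sig = as.numeric(y) - 1, dup = 2 * (as.numeric(y) - 1))
  q2 <- cross_validate_q2(X, y, model_spec("plsda", n_components = 1),
                          k_folds = 5, seed = 1)
  expect_equal(as.numeric(q2), 1, tolerance = 1e-8)

  d <- random_two_class(10, 6, seed = 13)
  spec <- model_spec("plsda", n_components = 2)
  q2b <- as.numeric(cross_validate_q2(d$X, d$y, spec, 7, seed = 2))
  r2y <- fit_plsda(d$X, d$y, 2)$r2y
  expect_lte(q2b, r2y)
})

test_that("Q2 is deterministic under the fold seed", {
  d <- random_two_class(10, 6, seed = 17)
  spec <- model_spec("plsda", n_components = 2)
  expect_identical(cross_validate_q2(d$X, d$y, spec, 7, seed = 5),
                   cross_validate_q2(d$X, d$y, spec, 7, seed = 5))
})

test_that("Q2 on pure noise is near or below zero", {
  q2s <- vapply(1:20, function(seed) {
    d <- random_two_class(25, 10, seed = 100 + seed)
    as.numeric(cross_validate_q2(d$X, d$y, model_spec("plsda", 2), 7,
                                 seed = seed))
  }, 0)
  expect_lt(median(q2s), 0.1)
})

test_that("the model refit is invariant under the identity permutation", {
  d <- random_two_class(8, 5, seed = 21)
  spec <- model_spec("plsda", n_components = 2)
  m1 <- nmrbiomark:::fit_spec_model(d$X, d$y, spec)
  m2 <- nmrbiomark:::fit_spec_model(d$X, d$y[seq_along(d$y)], spec)
  expect_identical(m1$r2y, m2$r2y)
})

test_that("a clearly separated cohort attains the minimum permutation p", {
  set.seed(31)
  y <- factor(rep(c("control", "case"), each = 10),
              levels = c("control", "case"))
  X <- cbind(sig = as.numeric(y) - 1 + rnorm(20, sd = 0.05),
             matrix(rnorm(60), 20, 3))
  pt <- permutation_test(X, y, model_spec("plsda", 1), n_perm = 100,
                         k_folds = 5, seed = 3)
  expect_equal(pt$p_q2, 1 / 101)
  expect_equal(pt$p_r2y, 1 / 101)
  expect_identical(nrow(pt$permuted), 100L)
})
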