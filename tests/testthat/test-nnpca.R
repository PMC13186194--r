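# Nonnegative PCA engine.

centered <- function(vals) scale(vals, center = TRUE, scale = FALSE)

test_that("projection onto the nonnegative unit sphere is total and exact", {
  expect_equal(project_nonneg_unit(c(3, 4, 0)), c(0.6, 0.8, 0))
  expect_equal(project_nonneg_unit(c(0, 5)), c(0, 1))
  # all-nonpositive input falls back to the argmax indicator, first on ties
  expect_equal(project_nonneg_unit(c(-1, -2)), c(1, 0))
  expect_equal(project_nonneg_unit(c(-3, -3)), c(1, 0))
  expect_error(project_nonneg_unit(numeric(0)), "non-empty")
})

test_that("two perfectly correlated equal-variance genes share the axis equally", {
  g <- rnorm(40)
  X <- centered(cbind(a = g, b = g))
  fit <- fit_nnpca(X, K = 1)
  expect_equal(unname(fit$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-7)
  expect_equal(fit$varexp[1], 1, tolerance = 1e-9)
})

test_that("anti-correlated genes force the axis onto the dominant gene", {
  withr::with_seed(7, {
    g <- rnorm(60, sd = 2)              # gene 1 has 4x the variance of gene 2
    X <- centered(cbind(a = g, b = -g / 2))
  })
  fit <- fit_nnpca(X, K = 1)
  # the classical (+,-) axis is infeasible; loading concentrates on gene 1
  expect_equal(unname(fit$loadings[, 1]), c(1, 0), tolerance = 1e-6)
  # and beats a dense random search over the nonnegative sphere
  best_random <- oracle_nnpca_var(X, n_dirs = 2e4, seed = 1)
  expect_gte(var(fit$scores[, 1]), 0.999 * best_random)
})

test_that("a planted nonnegative rank-1 program is recovered", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      w <- project_nonneg_unit(runif(6, 0.2, 1))
      t <- rnorm(80, sd = 3)
      X <- centered(tcrossprod(t, w) + matrix(rnorm(80 * 6, sd = 0.1), 80, 6))
    })
    fit <- fit_nnpca(X, K = 1)
    expect_gte(sum(fit$loadings[, 1] * w), 0.99)
  }
})

test_that("solver matches or beats random nonnegative search on small problems", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      p <- sample(4:6, 1)
      X <- centered(matrix(rnorm(60 * p), 60, p) %*%
                      matrix(rnorm(p * p), p, p))
    })
    fit <- fit_nnpca(X, K = 1)
    expect_gte(var(fit$scores[, 1]),
               0.99 * oracle_nnpca_var(X, n_dirs = 2e4, seed = seed))
  }
})

test_that("nnPCA reduces to classical PCA when the leading eigenvector is nonnegative", {
  withr::with_seed(11, {
    v <- project_nonneg_unit(runif(5, 0.5, 1))
    t <- rnorm(200, sd = 4)
    X <- centered(tcrossprod(t, v) + matrix(rnorm(200 * 5, sd = 0.3), 200, 5))
  })
  pc <- prcomp(X, center = FALSE)
  v1 <- pc$rotation[, 1]
  if (sum(v1) < 0) v1 <- -v1
  expect_true(all(v1 >= 0))            # guard: spike dominates, eigvec positive
  fit <- fit_nnpca(X, K = 1)
  expect_gte(sum(fit$loadings[, 1] * v1), 1 - 1e-6)
  evs <- pc$sdev^2
  expect_equal(fit$varexp[1], evs[1] / sum(evs), tolerance = 1e-6)
})

test_that("loadings are nonnegative unit vectors and varexp is non-increasing", {
  for (seed in 1:4) {
    withr::with_seed(seed, X <- centered(matrix(rnorm(50 * 8), 50, 8)))
    fit <- fit_nnpca(X, K = 4)
    expect_true(all(fit$loadings >= 0))
    expect_equal(unname(colSums(fit$loadings^2)), rep(1, 4), tolerance = 1e-9)
    expect_true(all(diff(fit$varexp) <= 1e-12))
    expect_lte(sum(fit$varexp), 1 + 1e-9)
  }
})

test_that("fits are bit-identical under identical inputs and seed", {
  withr::with_seed(3, X <- centered(matrix(rnorm(40 * 6), 40, 6)))
  f1 <- fit_nnpca(X, K = 3, seed = 5, restarts = 2)
  f2 <- fit_nnpca(X, K = 3, seed = 5, restarts = 2)
  expect_identical(f1, f2)
})

test_that("domain errors are raised for bad K and uncentered input", {
  X <- centered(matrix(rnorm(30 * 4), 30, 4))
  expect_error(fit_nnpca(X, K = 5), "K")
  expect_error(fit_nnpca(matrix(rnorm(30 * 4) + 5, 30, 4), K = 1),
               "column-centered")
})

test_that("variance_explained reproduces classical eigenvalue shares", {
  withr::with_seed(9, X <- centered(matrix(rnorm(60 * 5), 60, 5)))
  pc <- prcomp(X, center = FALSE)
  fr <- variance_explained(X, pc$x[, 1:3])
  evs <- pc$sdev^2
  expect_equal(unname(fr), (evs / sum(evs))[1:3], tolerance = 1e-10)
  expect_error(variance_explained(matrix(0, 10, 2), matrix(0, 10, 1)),
               "zero total variance")
  # single gene, single axis: the axis is everything
  x1 <- centered(matrix(rnorm(20), 20, 1))
  expect_equal(unname(variance_explained(x1, fit_nnpca(x1, K = 1)$scores)), 1)
})

test_that("top_loading_genes ranks by loading with alphabetical tie-break", {
  model <- structure(list(loadings = matrix(c(0.9, 0.3, 0.3, 0),
                                            dimnames = list(c("VIM", "ZEB1", "CDH2", "ZERO"),
                                                            "PC1"),
                                            ncol = 1)),
                     class = "nnpca_model")
  top <- top_loading_genes(model, 1, 2)
  expect_equal(top$gene, c("VIM", "CDH2"))
  # zero loadings never appear even when n is generous
  all3 <- top_loading_genes(model, 1, 10)
  expect_equal(nrow(all3), 3)
  expect_false("ZERO" %in% all3$gene)
  expect_error(top_loading_genes(model, 2, 5), "pc")
})
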