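test_that("sample splitting is balanced, disjoint and reproducible", {
  x <- matrix(rbinom(2552 * 3, 1, 0.5), 2552)
  h <- split_sample(x, seed = 1)
  expect_equal(nrow(h$first), 1276)
  expect_equal(nrow(h$second), 1276)
  x5 <- matrix(0, 5, 2)
  h5 <- split_sample(x5, seed = 2)
  expect_setequal(c(nrow(h5$first), nrow(h5$second)), c(3, 2))
  h2 <- split_sample(x, seed = 1)
  expect_identical(h$idx_first, h2$idx_first)
})

test_that("tetrachoric estimates match a likelihood grid-search oracle", {
  grid_oracle <- function(x, y) {
    t1 <- qnorm(1 - mean(x)); t2 <- qnorm(1 - mean(y))
    tab <- table(factor(x, 0:1), factor(y, 0:1))
    rhos <- seq(-0.999, 0.999, by = 1e-3)
    ll <- vapply(rhos, function(r) shortform:::tetra_loglik(r, tab, t1, t2), 0)
    rhos[which.max(ll)]
  }
  set.seed(14)
  for (rho in c(-0.4, 0.2, 0.6)) {
    z <- matrix(rnorm(4000), 2000) %*% chol(matrix(c(1, rho, rho, 1), 2))
    x <- as.integer(z[, 1] > -0.8); y <- as.integer(z[, 2] > -0.3)
    est <- tetrachoric(x, y)
    expect_false(est$clamped)
    expect_equal(est$rho, grid_oracle(x, y), tolerance = 2e-3)
  }
})

test_that("independent items have near-zero tetrachoric correlation", {
  set.seed(3)
  x <- rbinom(50000, 1, 0.7); y <- rbinom(50000, 1, 0.4)
  expect_lt(abs(tetrachoric(x, y)$rho), 0.02)
})

test_that("perfect association is clamped and flagged", {
  set.seed(6)
  x <- rbinom(400, 1, 0.6)
  est <- tetrachoric(x, x)
  expect_true(est$clamped)
  expect_equal(abs(est$rho), 0.999)
  M <- tetrachoric_matrix(cbind(a = x, b = x, c = rbinom(400, 1, 0.5)))
  expect_true(M$clamped["a", "b"])
  expect_true(all(eigen(M$rho, symmetric = TRUE,
                        only.values = TRUE)$values >= -1e-8))
})

test_that("scree eigenvalues satisfy trace and closed-form identities", {
  expect_equal(scree_eigenvalues(diag(12)), rep(1, 12))
  R <- matrix(0.49, 12, 12); diag(R) <- 1
  ev <- scree_eigenvalues(R)
  expect_equal(ev[1], 1 + 11 * 0.49, tolerance = 1e-10)
  expect_equal(ev[-1], rep(0.51, 11), tolerance = 1e-10)
  set.seed(10)
  A <- cov2cor(crossprod(matrix(rnorm(144), 12)))
  expect_equal(sum(scree_eigenvalues(A)), 12, tolerance = 1e-8)
})

test_that("the single-factor fit recovers an exact one-factor structure", {
  lam <- rep(0.7, 9)
  R <- tcrossprod(lam); diag(R) <- 1
  sol <- fit_single_factor(R)
  expect_equal(sol$loadings, lam, tolerance = 1e-6)
  expect_lt(sol$srmr, 1e-6)
  expect_false(sol$heywood)
  # sign canonicalization: mean loading positive
  expect_gt(mean(fit_single_factor(R)$loadings), 0)
  # no common factor: loadings near zero
  sol0 <- fit_single_factor(diag(6))
  expect_lt(max(abs(sol0$loadings)), 1e-4)
})

test_that("one-factor binary data shows the unidimensional scree signature", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    lam <- runif(12, 0.3, 0.8)
    th <- rnorm(5000)
    x <- sapply(1:12, function(j)
      as.integer(lam[j] * th + sqrt(1 - lam[j]^2) * rnorm(5000) > -0.7))
    ev <- scree_eigenvalues(tetrachoric_matrix(x))
    hits <- hits + (ev[1] > 1 && all(ev[-1] < 1))
  }
  expect_gte(hits, 9)
})

test_that("the split-sample screen reports a one-factor decision", {
  set.seed(20)
  lam <- runif(12, 0.4, 0.8)
  th <- rnorm(2000)
  x <- sapply(1:12, function(j)
    as.integer(lam[j] * th + sqrt(1 - lam[j]^2) * rnorm(2000) > -0.5))
  scr <- dimensionality_screen(x, seed = 2)
  expect_true(scr$one_factor)
  expect_equal(scr$n_explore + scr$n_confirm, 2000)
  expect_true(all(abs(scr$solution$loadings) <= 1))
})
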