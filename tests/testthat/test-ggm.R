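test_that("glasso limits: full shrinkage and unpenalized inverse", {
  S <- random_cor(5)
  lam_max <- max(abs(S[upper.tri(S)]))
  fit <- glasso_fit(S, lam_max * 1.001)
  off <- fit$Theta[upper.tri(fit$Theta)]
  expect_true(all(off == 0))
  fit0 <- glasso_fit(S, 0)
  expect_equal(fit0$Theta, solve(S), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("glasso agrees with an independent convex solver and passes KKT", {
  set.seed(11)
  for (i in 1:20) {
    p <- sample(3:6, 1)
    S <- random_cor(p)
    lam <- runif(1, 0.02, 0.4)
    fit <- glasso_fit(S, lam)
    ref <- admm_glasso(S, lam)
    expect_lt(max(abs(fit$Theta - ref)), 1e-4)
    expect_lt(glasso_kkt(fit$Theta, S, lam), 1e-4)
    # solution is positive definite
    expect_gt(min(eigen(fit$Theta, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("precision_to_partial evaluates the standard identity", {
  Theta <- matrix(c(2, -1, -1, 2), 2)
  expect_equal(precision_to_partial(Theta)[1, 2], 0.5)
  expect_equal(precision_to_partial(diag(3)), matrix(0, 3, 3))
  set.seed(12)
  A <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  W <- precision_to_partial(A)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(W[i, j], -A[i, j] / sqrt(A[i, i] * A[j, j]),
                 tolerance = 1e-12)
  }
  expect_error(precision_to_partial(matrix(c(-1, 0, 0, 1), 2)), "diagonal")
})

test_that("EBIC formula and limits", {
  expect_equal(ebic(-50, 4, 200, 8, 0), 100 + 4 * log(200))
  expect_equal(ebic(-77, 0, 100, 10, 0.5), 154)
  expect_equal(ebic(-100, 3, 500, 10, 0.5),
               200 + 3 * log(500) + 6 * log(10), tolerance = 1e-12)
})

test_that("estimate_network selects the EBIC argmin over the path", {
  set.seed(13)
  Theta <- make_chain_precision(8, 0.3)
  X <- mvn_sample(500, solve(Theta))
  fit <- estimate_network(X)
  expect_s3_class(fit, "network_model")
  expect_equal(nrow(fit$path), 100)
  expect_equal(fit$ebic_value, min(fit$path$ebic), tolerance = 1e-9)
  # tie-break toward larger lambda: selected lambda is the largest argmin
  argmins <- fit$path$lambda[fit$path$ebic <= min(fit$path$ebic) + 1e-9]
  expect_equal(fit$lambda_selected, max(argmins))
  # weight matrix sanity
  expect_equal(diag(fit$W), rep(0, 8), ignore_attr = TRUE)
  expect_true(all(abs(fit$W) < 1))
  expect_equal(fit$W, t(fit$W))
  # zero pattern matches the precision matrix off-diagonal
  off <- upper.tri(fit$W)
  expect_identical(fit$W[off] == 0, fit$Theta[off] == 0)
})

test_that("edge count along the path is non-increasing in lambda", {
  set.seed(14)
  X <- mvn_sample(300, solve(make_chain_precision(10, 0.3)))
  fit <- estimate_network(X)
  # path stored with descending lambda: edges must not decrease
  expect_true(all(diff(fit$path$edges) >= -1))  # +/-1 numerical flips allowed
})

test_that("estimation is invariant to column rescaling", {
  set.seed(15)
  X <- mvn_sample(300, solve(make_chain_precision(6, 0.3)))
  sc <- c(1, 10, 0.1, 100, 5, 0.01)
  fit1 <- estimate_network(X, preprocess = FALSE)
  fit2 <- estimate_network(sweep(X, 2, sc, "*"), preprocess = FALSE)
  expect_equal(fit1$W, fit2$W, tolerance = 1e-10)
})

test_that("every model on the selected path passes the KKT check", {
  set.seed(16)
  X <- mvn_sample(200, solve(make_chain_precision(5, 0.35)))
  S <- cor(scale(X))
  for (lam in c(0.3, 0.1, 0.05, 0.02)) {
    fit <- glasso_fit(S, lam)
    expect_lt(glasso_kkt(fit$Theta, S, lam), 1e-4)
  }
})

test_that("independent data give an empty or near-empty selected network", {
  set.seed(17)
  spurious <- replicate(20, {
    X <- matrix(rnorm(2000 * 10), 2000, 10)
    W <- estimate_network(X, return_path = FALSE)$W
    sum(W[upper.tri(W)] != 0)
  })
  expect_gte(mean(spurious <= 1), 0.95)
})

test_that("chain-graph truth is recovered at moderate n", {
  set.seed(18)
  Theta <- make_chain_precision(10, 0.3)
  ok <- replicate(20, {
    X <- mvn_sample(2000, solve(Theta))
    r <- recovery_rates(estimate_network(X, return_path = FALSE)$W, Theta)
    r$sensitivity >= 8 / 9 && r$false_edges <= 1
  })
  expect_gte(mean(ok), 0.9)
})
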