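test_that("identical groups give zero statistics and p-values of 1", {
  set.seed(21)
  X <- mvn_sample(120, solve(make_chain_precision(5, 0.3)))
  res <- nct(X, X, n_permutations = 30)
  expect_equal(res$s_observed, 0)
  expect_equal(res$m_observed, 0)
  expect_equal(res$s_pvalue, 1)
  expect_equal(res$m_pvalue, 1)
})

test_that("p-values use the add-one convention and lie in (0, 1]", {
  set.seed(22)
  Sig <- solve(make_chain_precision(5, 0.3))
  res <- nct(mvn_sample(150, Sig), mvn_sample(150, Sig),
             n_permutations = 40, seed = 1)
  K <- res$n_permutations
  expect_true(res$s_pvalue >= 1 / (K + 1) && res$s_pvalue <= 1)
  expect_equal(res$s_pvalue * (K + 1), round(res$s_pvalue * (K + 1)),
               tolerance = 1e-9)
  expect_gte(res$m_observed, max(abs(res$W1 - res$W2)))
})

test_that("swapping the two groups leaves the test invariant", {
  set.seed(23)
  Sig <- solve(make_chain_precision(6, 0.3))
  x1 <- mvn_sample(100, Sig)
  x2 <- mvn_sample(100, Sig)
  a <- nct(x1, x2, n_permutations = 50, seed = 7)
  b <- nct(x2, x1, n_permutations = 50, seed = 7)
  expect_equal(a$s_observed, b$s_observed)
  expect_equal(a$m_observed, b$m_observed)
  expect_equal(a$s_pvalue, b$s_pvalue)
  expect_equal(a$m_pvalue, b$m_pvalue)
  # also under the pair-split scheme
  pr <- sprintf("p%03d", 1:100)
  ap <- nct(x1, x2, n_permutations = 50, seed = 7, pairs1 = pr, pairs2 = pr)
  bp <- nct(x2, x1, n_permutations = 50, seed = 7, pairs1 = pr, pairs2 = pr)
  expect_equal(ap$s_pvalue, bp$s_pvalue)
  expect_equal(ap$m_pvalue, bp$m_pvalue)
})

test_that("a strong group difference is detected", {
  set.seed(24)
  x1 <- mvn_sample(500, solve(make_chain_precision(6, 0.25, boost = 1.8)))
  x2 <- mvn_sample(500, solve(make_chain_precision(6, 0.25)))
  res <- nct(x1, x2, n_permutations = 100, seed = 1)
  expect_lt(res$s_pvalue, 0.05)
})

test_that("edge-level tests are consistent and refocusable", {
  set.seed(25)
  x1 <- mvn_sample(400, solve(make_chain_precision(5, 0.25, boost = 1.8)))
  x2 <- mvn_sample(400, solve(make_chain_precision(5, 0.25)))
  colnames(x1) <- colnames(x2) <- paste0("N", 1:5)
  res <- nct(x1, x2, n_permutations = 60, seed = 2)
  et <- res$edge_tests
  expect_equal(nrow(et), choose(5, 2))
  expect_true(all(et$p_holm >= et$p_raw - 1e-12))
  expect_equal(et$diff, abs(et$w1 - et$w2))
  sub <- edge_invariance_tests(res, nodes = "N1")
  expect_true(all(sub$node1 == "N1" | sub$node2 == "N1"))
  expect_true(all(sub$p_corrected <= 1))
})

test_that("input validation catches misuse", {
  set.seed(26)
  X <- mvn_sample(50, diag(4))
  expect_error(nct(X, X[, 1:3], n_permutations = 5), "same variables")
  expect_error(nct(X, X, n_permutations = 0), "n_permutations")
  expect_error(nct(X, X, n_permutations = 5, permutation = "pair"),
               "pairs1")
  expect_error(nct(X, X, n_permutations = 5,
                   pairs1 = rep("a", 50), pairs2 = rep(c("a", "b"), 25)),
               "one member")
})
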