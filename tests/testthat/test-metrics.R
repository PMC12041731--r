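make_W <- function(p, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(p * p, -0.4, 0.4), p)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

test_that("strength and expected influence are the (absolute) row sums", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- -0.2
  expect_equal(strength(W, 1), 0.5, ignore_attr = TRUE)
  expect_equal(expected_influence(W, 1), 0.1, ignore_attr = TRUE)
  expect_equal(strength(W, 2), 0.3, ignore_attr = TRUE)
  # isolated node
  W2 <- matrix(0, 3, 3)
  expect_equal(strength(W2, 3), 0, ignore_attr = TRUE)
  # brute-force agreement on a random matrix
  W6 <- make_W(6)
  for (i in 1:6) {
    expect_equal(strength(W6, i), sum(abs(W6[i, ])), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(expected_influence(W6, i), sum(W6[i, ]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("global strength sums unique edges and ties to node strength", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- -0.25
  expect_equal(global_strength(W), 0.75)
  expect_equal(global_strength(matrix(0, 4, 4)), 0)
  for (s in 1:5) {
    Wr <- make_W(7, seed = s)
    expect_equal(global_strength(Wr), sum(abs(Wr[upper.tri(Wr)])),
                 tolerance = 1e-12)
    expect_equal(sum(strength(Wr)), 2 * global_strength(Wr),
                 tolerance = 1e-12)
  }
})

test_that("EI equals strength on all-positive networks", {
  W <- abs(make_W(6, seed = 2))
  diag(W) <- 0
  expect_equal(expected_influence(W), strength(W), tolerance = 1e-12)
  expect_true(all(strength(make_W(6, 3)) >=
                    abs(expected_influence(make_W(6, 3))) - 1e-12))
})

test_that("z-standardization follows the sample-SD convention", {
  z <- z_standardize(c(0, 10))
  expect_equal(z, (c(0, 10) - 5) / sd(c(0, 10)))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_warning(z0 <- z_standardize(rep(3, 4)), "constant")
  expect_equal(z0, rep(0, 4))
  set.seed(3)
  x <- rnorm(10)
  xs <- z_standardize(x)
  expect_equal(z_standardize(xs), xs, tolerance = 1e-12)
})

test_that("centralities are equivariant under node permutation", {
  W <- make_W(8, seed = 4)
  perm <- sample(8)
  Wp <- W[perm, perm]
  expect_equal(strength(Wp), strength(W)[perm], tolerance = 1e-12)
  expect_equal(expected_influence(Wp), expected_influence(W)[perm],
               tolerance = 1e-12)
})

test_that("centrality table flags covariates and z-standardizes per network", {
  reg <- variable_registry()
  W <- make_W(39, seed = 5)
  dimnames(W) <- list(reg$name, reg$name)
  tab <- centrality_table(W, registry = reg)
  expect_equal(nrow(tab), 39)
  expect_equal(sum(tab$is_covariate), 2)
  expect_equal(mean(tab$z_strength), 0, tolerance = 1e-12)
  expect_equal(sd(tab$z_strength), 1, tolerance = 1e-12)
})
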