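test_that("chain precision construction gives the stated partial correlations", {
  expect_equal(make_chain_precision(3, 0, 1), diag(3))
  Theta <- make_chain_precision(2, 0.4)
  expect_equal(precision_to_partial(Theta)[1, 2], 0.4)
  # boosted chain stays positive definite (dense eigensolver check)
  Theta10 <- make_chain_precision(10, 0.3, boost = 1.5)
  ev <- eigen(Theta10, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_error(make_chain_precision(10, 0.6, boost = 1.5), "positive definite")
})

test_that("registry has the documented battery structure", {
  reg <- variable_registry()
  expect_equal(nrow(reg), 39)
  expect_equal(as.vector(table(reg$category)[c("depressive", "cognitive",
                                               "intellectual", "physical",
                                               "social", "covariate")]),
               c(9L, 6L, 8L, 6L, 8L, 2L))
  expect_false(anyDuplicated(reg$name) > 0)
  expect_error(validate_registry(data.frame(name = c("a", "a"),
                                            category = "generic",
                                            scale = "continuous")),
               "unique")
})

test_that("generated tables have complete like-sex pairs and are reproducible", {
  cfg <- test_twin_config(p = 5, n_pairs = 30)
  tw <- generate_twin_pairs(cfg)
  expect_equal(nrow(tw), 4 * 30 * 2)
  counts <- table(tw$pair_id)
  expect_true(all(counts == 2))
  expect_true(all(tapply(tw$twin_index, tw$pair_id, function(z)
    setequal(z, 1:2))))
  hom <- tapply(paste(tw$zygosity, tw$gender), tw$pair_id,
                function(z) length(unique(z)))
  expect_true(all(hom == 1))
  # determinism
  tw2 <- generate_twin_pairs(cfg)
  expect_identical(tw, tw2)
})

test_that("cross-twin correlations follow the ACE structure", {
  # h2 = 0, c2 = 0: co-twins independent
  cfg0 <- test_twin_config(p = 4, n_pairs = 2000, h2 = 0, c2 = 0, seed = 5)
  tw0 <- generate_twin_pairs(cfg0)
  st0 <- split_strata(tw0)
  ct_cor <- function(stratum) {
    X <- twin_matrix(stratum)
    a <- X[stratum$twin_index == 1, , drop = FALSE]
    b <- X[stratum$twin_index == 2, , drop = FALSE]
    diag(cor(a, b))
  }
  expect_true(all(abs(ct_cor(st0$MZ_F)) < 0.05))
  # h2 = 0.6, c2 = 0.2: rho_MZ = 0.8, rho_DZ = 0.5 (Monte-Carlo oracle)
  cfg <- test_twin_config(p = 4, n_pairs = 5000, h2 = 0.6, c2 = 0.2, seed = 6)
  tw <- generate_twin_pairs(cfg)
  st <- split_strata(tw)
  expect_true(all(abs(ct_cor(st$MZ_M) - 0.8) < 0.03))
  expect_true(all(abs(ct_cor(st$DZ_M) - 0.5) < 0.03))
})

test_that("designated columns come out skewed", {
  reg <- variable_registry(p = 6)
  cfg <- twin_config(n_pairs = c(MZ_F = 300, DZ_F = 1, MZ_M = 1, DZ_M = 1),
                     registry = reg,
                     theta_f = make_chain_precision(6, 0.3),
                     theta_m = make_chain_precision(6, 0.3),
                     skew_columns = c("V05", "V06"), seed = 9)
  tw <- generate_twin_pairs(cfg)
  st <- split_strata(tw)$MZ_F
  expect_gt(abs(sample_skewness(st$V05)), 1)
  expect_gt(abs(sample_skewness(st$V06)), 1)
  expect_lt(abs(sample_skewness(st$V01)), 1)
})

test_that("swapping twin labels leaves pooled summary statistics unchanged", {
  cfg <- test_twin_config(p = 4, n_pairs = 50)
  tw <- generate_twin_pairs(cfg)
  swapped <- tw
  swapped$twin_index <- 3L - swapped$twin_index
  X1 <- twin_matrix(tw[order(tw$pair_id, tw$twin_index), ])
  X2 <- twin_matrix(swapped[order(swapped$pair_id, swapped$twin_index), ])
  expect_equal(colMeans(X1), colMeans(X2))
  expect_equal(cov(X1), cov(X2))
})

test_that("invalid configurations are rejected", {
  expect_error(test_twin_config(h2 = 0.8, c2 = 0.4), "h2 \\+ c2")
  reg <- variable_registry(p = 4)
  expect_error(
    twin_config(n_pairs = c(MZ_F = 5, DZ_F = 5, MZ_M = 5, DZ_M = 5),
                registry = reg,
                theta_f = diag(4) * -1, theta_m = diag(4)),
    "positive definite")
  expect_error(
    twin_config(n_pairs = c(MZ_F = 5), registry = reg,
                theta_f = diag(4), theta_m = diag(4)),
    "n_pairs")
})
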