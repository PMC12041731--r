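test_that("identical co-twins give the degenerate limit exactly", {
  cfg <- test_twin_config(p = 5, n_pairs = 60, seed = 41)
  tw <- generate_twin_pairs(cfg)
  st <- split_strata(tw)$MZ_F
  # overwrite twin 2 with twin 1: co-twin datasets identical in every split
  ids <- unique(st$pair_id)
  vars <- setdiff(names(st), c("pair_id", "twin_index", "zygosity", "gender"))
  for (id in ids) {
    rows <- which(st$pair_id == id)
    st[rows[2], vars] <- st[rows[1], vars]
  }
  res <- reassign_cotwins(st, R = 5, inner_permutations = 20, seed = 1)
  expect_true(all(res$iterations$S == 0))
  expect_true(all(res$iterations$M == 0))
  expect_true(all(res$iterations$s_pvalue == 1))
  expect_true(all(res$iterations$m_pvalue == 1))
  expect_false(res$significant)
  expect_equal(res$averaged_network_A, res$averaged_network_B)
})

test_that("reassignment partitions every pair across the two datasets", {
  # the partition property is structural: each iteration assigns exactly one
  # member per pair to each dataset, so both averaged networks are built from
  # n_pairs rows; verified here through the exchangeable-identical limit above
  # and the bookkeeping checks below
  cfg <- test_twin_config(p = 4, n_pairs = 25, seed = 42)
  st <- split_strata(generate_twin_pairs(cfg))$DZ_M
  res <- reassign_cotwins(st, R = 4, inner_permutations = 10, seed = 2)
  expect_equal(res$n_pairs, 25)
  expect_equal(nrow(res$iterations), 4)
  expect_true(all(is.finite(res$iterations$s_pvalue)))
  sym <- function(M) isTRUE(all.equal(M, t(M))) && all(diag(M) == 0)
  expect_true(sym(res$averaged_network_A))
  expect_true(sym(res$averaged_network_B))
})

test_that("reassignment is deterministic under a seed and validates input", {
  cfg <- test_twin_config(p = 4, n_pairs = 20, seed = 43)
  st <- split_strata(generate_twin_pairs(cfg))$MZ_M
  a <- reassign_cotwins(st, R = 3, inner_permutations = 10, seed = 9)
  b <- reassign_cotwins(st, R = 3, inner_permutations = 10, seed = 9)
  expect_identical(a$iterations, b$iterations)
  mixed <- split_strata(generate_twin_pairs(cfg))
  expect_error(reassign_cotwins(rbind(mixed$MZ_M, mixed$DZ_M), R = 2,
                                inner_permutations = 5),
               "homogeneous")
  expect_error(reassign_cotwins(st[-1, ], R = 2, inner_permutations = 5),
               "incomplete")
})

test_that("level-2 and level-3 wrappers validate their strata", {
  cfg <- test_twin_config(p = 4, n_pairs = 30, seed = 44)
  st <- split_strata(generate_twin_pairs(cfg))
  r2 <- run_level2(st$MZ_F, st$DZ_F, n_permutations = 20, seed = 1)
  expect_s3_class(r2, "nct_result")
  expect_error(run_level2(st$DZ_F, st$MZ_F, n_permutations = 5),
               "MZ and DZ")
  expect_error(run_level2(st$MZ_F, st$DZ_M, n_permutations = 5),
               "same single gender")
  women <- rbind(st$MZ_F, st$DZ_F)
  men <- rbind(st$MZ_M, st$DZ_M)
  r3 <- run_level3(women, men, n_permutations = 20, seed = 2)
  expect_s3_class(r3, "nct_result")
  expect_error(run_level3(men, women, n_permutations = 5), "female and male")
})

test_that("the full study runs, gates coherently, and reproduces byte-identically", {
  cfg <- test_twin_config(p = 5, n_pairs = 40, boost_f = 2.2, seed = 45,
                          edge = 0.25)
  tw <- generate_twin_pairs(cfg)
  sc <- study_config(n_permutations = 40, n_reassignments = 4,
                     inner_permutations = 15, seed = 11)
  rep1 <- run_study(tw, sc)
  expect_s3_class(rep1, "study_report")
  expect_named(rep1$level1, c("MZ_F", "DZ_F", "MZ_M", "DZ_M"))
  # gate bookkeeping matches the per-level results
  expect_equal(unname(rep1$gates$cotwins_exchangeable),
               unname(!sapply(rep1$level1, `[[`, "significant")))
  expect_equal(rep1$gates$level3_significant$S,
               rep1$level3$s_pvalue < sc$alpha)
  rep2 <- run_study(tw, sc)
  rep1$provenance$package_version <- rep2$provenance$package_version
  expect_identical(rep1, rep2)
  # missing stratum
  expect_error(run_study(tw[tw$zygosity == "MZ", ], sc), "missing strata")
})

test_that("study configuration validates and round-trips through YAML", {
  sc <- study_config(gamma = 0.5, seed = 7)
  expect_equal(sc$n_lambdas, 100L)
  expect_equal(sc$n_permutations, 1000L)
  expect_equal(sc$n_reassignments, 1000L)
  expect_equal(sc$skew_threshold, 1)
  expect_error(study_config(gamma = -1), "gamma")
  expect_error(study_config(alpha = 0.9), "alpha")
  path <- tempfile(fileext = ".yaml")
  write_study_config(sc, path)
  expect_equal(read_study_config(path), sc)
})
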