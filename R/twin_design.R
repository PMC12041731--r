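#' Co-twin reassignment analysis (level 1)
#'
#' Within one gender-by-zygosity stratum, the two members of every pair
#' are repeatedly reallocated to two datasets by independent fair coins;
#' each reallocation is compared with a pair-respecting NCT, and the
#' estimated per-group networks accumulate into two running elementwise
#' means ("averaged co-twin networks"). The distributions of the
#' per-iteration S and M p-values summarize whether co-twins differ
#' beyond the arbitrariness of twin labelling.
#'
#' A stratum is declared significantly different when the proportion of
#' iterations with p < `alpha` exceeds
#' `alpha + 2 * sqrt(alpha * (1 - alpha) / R)` — a conservative binomial
#' band around the rate expected under exchangeable co-twins.
#'
#' @param stratum A twin-pair table homogeneous in zygosity and gender.
#' @param R Number of reassignments (default 1000).
#' @param inner_permutations Permutations inside each NCT (default 1000).
#' @param alpha Significance level used for the summary (default 0.05).
#' @param seed Optional integer seed.
#' @param registry Optional registry fixing the variable order.
#' @param ... Passed to [estimate_network()] via [nct()].
#' @return Object of class `reassignment_result`: per-iteration
#'   statistics, p-value summaries for S and M, the two averaged
#'   networks, and the significance decision.
#' @export
reassign_cotwins <- function(stratum, R = 1000, inner_permutations = 1000,
                             alpha = 0.05, seed = NULL, registry = NULL, ...) {
  if (R < 1) stop("R must be >= 1")
  .check_stratum(stratum)
  if (length(unique(stratum$zygosity)) != 1L ||
      length(unique(stratum$gender)) != 1L) {
    stop("stratum must be homogeneous in zygosity and gender")
  }
  if (!is.null(seed)) set.seed(seed)
  X <- twin_matrix(stratum, registry)
  ids <- sort(unique(stratum$pair_id))
  m <- length(ids)
  key <- paste(stratum$pair_id, stratum$twin_index)
  r1 <- match(paste(ids, 1L), key)
  r2 <- match(paste(ids, 2L), key)
  M1 <- X[r1, , drop = FALSE]
  M2 <- X[r2, , drop = FALSE]
  p <- ncol(X)
  iter_seeds <- sample.int(.Machine$integer.max, R)
  stats_tab <- data.frame(iteration = seq_len(R), S = NA_real_, M = NA_real_,
                          s_pvalue = NA_real_, m_pvalue = NA_real_)
  sumA <- sumB <- matrix(0, p, p)
  for (r in seq_len(R)) {
    coin <- stats::runif(m) < 0.5
    A <- M1
    B <- M2
    A[coin, ] <- M2[coin, , drop = FALSE]
    B[coin, ] <- M1[coin, , drop = FALSE]
    res <- nct(A, B, n_permutations = inner_permutations,
               seed = iter_seeds[r], pairs1 = ids, pairs2 = ids,
               permutation = "pair", edge_tests = FALSE, ...)
    stats_tab$S[r] <- res$s_observed
    stats_tab$M[r] <- res$m_observed
    stats_tab$s_pvalue[r] <- res$s_pvalue
    stats_tab$m_pvalue[r] <- res$m_pvalue
    sumA <- sumA + res$W1
    sumB <- sumB + res$W2
  }
  band <- alpha + 2 * sqrt(alpha * (1 - alpha) / R)
  summarize <- function(pv) {
    list(min = min(pv), q05 = unname(stats::quantile(pv, 0.05)),
         prop_below_alpha = mean(pv < alpha))
  }
  s_sum <- summarize(stats_tab$s_pvalue)
  m_sum <- summarize(stats_tab$m_pvalue)
  avgA <- sumA / R
  avgB <- sumB / R
  dimnames(avgA) <- dimnames(avgB) <- dimnames(res$W1)
  structure(list(
    n_reassignments = R, inner_permutations = inner_permutations,
    alpha = alpha, decision_band = band,
    zygosity = stratum$zygosity[1], gender = stratum$gender[1],
    n_pairs = m,
    iterations = stats_tab,
    s_summary = s_sum, m_summary = m_sum,
    significant = s_sum$prop_below_alpha > band ||
      m_sum$prop_below_alpha > band,
    averaged_network_A = avgA, averaged_network_B = avgB
  ), class = "reassignment_result")
}

#' @export
print.reassignment_result <- function(x, ...) {
  cat(sprintf("Co-twin reassignment (%s %s): %d pairs, R = %d\n",
              x$zygosity, x$gender, x$n_pairs, x$n_reassignments))
  cat(sprintf("  S p-values: min %.3f, prop < alpha %.3f\n",
              x$s_summary$min, x$s_summary$prop_below_alpha))
  cat(sprintf("  M p-values: min %.3f, prop < alpha %.3f\n",
              x$m_summary$min, x$m_summary$prop_below_alpha))
  cat("  significant difference among reassignments: ",
      x$significant, "\n", sep = "")
  invisible(x)
}

#' Zygosity comparison within gender (level 2)
#'
#' Pools both co-twins of every pair and compares the MZ and DZ networks
#' of one gender with a single NCT (pair-respecting permutation by
#' default, since co-twins are nested within groups here).
#'
#' @param stratum_mz,stratum_dz Twin-pair tables of the same gender.
#' @param n_permutations Permutations (default 1000).
#' @param seed Optional integer seed.
#' @param registry Optional registry fixing variable order.
#' @param permutation Permutation scheme (default `"pair"`).
#' @param ... Passed to [nct()].
#' @return An `nct_result`.
#' @export
run_level2 <- function(stratum_mz, stratum_dz, n_permutations = 1000,
                       seed = NULL, registry = NULL,
                       permutation = c("pair", "plain"), ...) {
  permutation <- match.arg(permutation)
  .check_stratum(stratum_mz)
  .check_stratum(stratum_dz)
  if (!all(stratum_mz$zygosity == "MZ") || !all(stratum_dz$zygosity == "DZ")) {
    stop("arguments must be the MZ and DZ strata, in that order")
  }
  g1 <- unique(stratum_mz$gender)
  g2 <- unique(stratum_dz$gender)
  if (length(g1) != 1L || !identical(g1, g2)) {
    stop("both strata must be of the same single gender")
  }
  nct(twin_matrix(stratum_mz, registry), twin_matrix(stratum_dz, registry),
      n_permutations = n_permutations, seed = seed,
      pairs1 = if (permutation == "pair") stratum_mz$pair_id else NULL,
      pairs2 = if (permutation == "pair") stratum_dz$pair_id else NULL,
      permutation = permutation, ...)
}

#' Gender comparison (level 3)
#'
#' Pools zygosity groups within gender and compares the female and male
#' networks with a single NCT. Edge-level results can afterwards be
#' focused on depressive-symptom nodes with [edge_invariance_tests()].
#'
#' @param women_table,men_table Pooled per-gender twin-pair tables.
#' @param n_permutations Permutations (default 1000).
#' @param seed Optional integer seed.
#' @param registry Optional registry fixing variable order.
#' @param permutation Permutation scheme (default `"pair"`).
#' @param ... Passed to [nct()].
#' @return An `nct_result`.
#' @export
run_level3 <- function(women_table, men_table, n_permutations = 1000,
                       seed = NULL, registry = NULL,
                       permutation = c("pair", "plain"), ...) {
  permutation <- match.arg(permutation)
  .check_stratum(women_table)
  .check_stratum(men_table)
  if (!all(women_table$gender == "F") || !all(men_table$gender == "M")) {
    stop("arguments must be the female and male tables, in that order")
  }
  nct(twin_matrix(women_table, registry), twin_matrix(men_table, registry),
      n_permutations = n_permutations, seed = seed,
      pairs1 = if (permutation == "pair") women_table$pair_id else NULL,
      pairs2 = if (permutation == "pair") men_table$pair_id else NULL,
      permutation = permutation, ...)
}

#' Run the full three-level twin comparison study
#'
#' Level 1: co-twin reassignment analyses within each of the four
#' gender-by-zygosity strata. Level 2: MZ vs DZ within each gender on the
#' pooled co-twins. Level 3: women vs men pooling zygosity. The pooling
#' logic is gated — level 2 is justified by the absence of co-twin
#' differences, level 3 by the absence of zygosity differences — but the
#' gates are advisory: every level is always computed and gate violations
#' are flagged in the report rather than stopping the analysis.
#'
#' @param table A twin-pair table containing all four strata.
#' @param config A [study_config()]; its fields supply all analysis
#'   parameters and the seed.
#' @param registry Optional registry fixing variable order.
#' @return Object of class `study_report` with elements `level1` (four
#'   `reassignment_result`s), `level2` (two `nct_result`s), `level3`
#'   (one `nct_result`), `gates`, and `provenance`.
#' @export
run_study <- function(table, config = study_config(), registry = NULL) {
  stopifnot(inherits(config, "study_config"))
  .check_stratum(table)
  strata <- split_strata(table)
  need <- c("MZ_F", "DZ_F", "MZ_M", "DZ_M")
  missing <- setdiff(need, names(strata))
  if (length(missing)) stop("missing strata: ", paste(missing, collapse = ", "))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, 7)
  est_args <- list(gamma = config$gamma, n_lambdas = config$n_lambdas,
                   skew_threshold = config$skew_threshold)
  alpha <- config$alpha

  level1 <- vector("list", 4)
  names(level1) <- need
  for (i in seq_along(need)) {
    level1[[i]] <- do.call(reassign_cotwins, c(list(
      strata[[need[i]]], R = config$n_reassignments,
      inner_permutations = config$inner_permutations,
      alpha = alpha, seed = seeds[i], registry = registry), est_args))
  }
  gate1 <- !vapply(level1, `[[`, logical(1), "significant")

  level2 <- list(
    F = do.call(run_level2, c(list(
      strata$MZ_F, strata$DZ_F, n_permutations = config$n_permutations,
      seed = seeds[5], registry = registry,
      permutation = config$permutation), est_args)),
    M = do.call(run_level2, c(list(
      strata$MZ_M, strata$DZ_M, n_permutations = config$n_permutations,
      seed = seeds[6], registry = registry,
      permutation = config$permutation), est_args))
  )
  gate2 <- vapply(level2, function(r) {
    r$s_pvalue >= alpha && r$m_pvalue >= alpha
  }, logical(1))

  women <- do.call(rbind, strata[c("MZ_F", "DZ_F")])
  men <- do.call(rbind, strata[c("MZ_M", "DZ_M")])
  level3 <- do.call(run_level3, c(list(
    women, men, n_permutations = config$n_permutations,
    seed = seeds[7], registry = registry,
    permutation = config$permutation), est_args))

  structure(list(
    level1 = level1,
    level2 = level2,
    level3 = level3,
    gates = list(
      cotwins_exchangeable = gate1,
      level2_justified = all(gate1),
      zygosity_invariant = gate2,
      level3_justified = all(gate2),
      level3_significant = list(S = level3$s_pvalue < alpha,
                                M = level3$m_pvalue < alpha)
    ),
    provenance = list(
      seed = config$seed, stage_seeds = seeds, config = unclass(config),
      n_per_stratum = vapply(strata, nrow, integer(1)),
      package_version = as.character(utils::packageVersion("twinnet"))
    )
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Three-level twin network comparison\n")
  cat("  Level 1 (co-twins exchangeable): ",
      paste(sprintf("%s=%s", names(x$gates$cotwins_exchangeable),
                    x$gates$cotwins_exchangeable), collapse = " "), "\n")
  for (g in names(x$level2)) {
    r <- x$level2[[g]]
    cat(sprintf("  Level 2 (%s, MZ vs DZ): S = %.3f (p = %.3f), M = %.3f (p = %.3f)\n",
                g, r$s_observed, r$s_pvalue, r$m_observed, r$m_pvalue))
  }
  r <- x$level3
  cat(sprintf("  Level 3 (women vs men): S = %.3f (p = %.3f), M = %.3f (p = %.3f)\n",
              r$s_observed, r$s_pvalue, r$m_observed, r$m_pvalue))
  invisible(x)
}

.check_stratum <- function(table) {
  if (!is.data.frame(table)) stop("expected a twin-pair data frame")
  if (!all(.meta_cols %in% names(table))) {
    stop("table must have columns: ", paste(.meta_cols, collapse = ", "))
  }
  if (nrow(table) == 0) stop("empty stratum")
  tab <- table(table$pair_id)
  if (any(tab != 2)) {
    stop("incomplete pairs: ", paste(utils::head(names(tab)[tab != 2], 5),
                                     collapse = ", "))
  }
  invisible(table)
}
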