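#' Permutation network comparison test
#'
#' Compares the networks of two independent groups with permutation
#' re-estimation. The observed statistics are the global strength
#' difference `S = |GS(W1) - GS(W2)|` and the maximum edge difference
#' `M = max_{i<j} |w1_ij - w2_ij|`. Group labels are then permuted
#' `n_permutations` times; every permutation re-runs the full estimation
#' pipeline (skew screen, nonparanormal step, EBIC-selected glasso) on
#' both permuted groups. p-values use the add-one convention
#' `(b + 1) / (K + 1)`. Per-edge invariance tests reuse the same draws
#' with Holm correction.
#'
#' Three permutation schemes are available. `"plain"` permutes
#' individuals freely (the classic test, valid for independent rows).
#' When twin-pair identifiers are supplied, `"pair"` respects the
#' within-pair dependence: if each pair has one member in each group
#' (a co-twin comparison) members are swapped within pairs; if pairs are
#' nested within groups (pooled zygosity or gender comparisons) whole
#' pairs are reallocated between groups. Pair-aware permutation keeps the
#' test exact when co-twins are correlated.
#'
#' @param data1,data2 Individuals x variables matrices with identical
#'   column sets.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param pairs1,pairs2 Optional pair identifiers (one per row) enabling
#'   pair-respecting permutation.
#' @param permutation `"plain"` or `"pair"`; defaults to `"pair"` when
#'   identifiers are supplied, else `"plain"`.
#' @param edge_tests Retain per-edge permutation tests (default TRUE).
#' @param max_failure_rate Abort if more than this fraction of
#'   permutations fail to estimate (default 0.05).
#' @param gamma,n_lambdas,lambda_min_ratio,skew_threshold Estimation
#'   settings, as in [estimate_network()]; every permutation re-runs the
#'   full pipeline with them.
#' @return Object of class `nct_result` with observed statistics,
#'   p-values, the retained null distributions, per-edge tests and the
#'   two estimated group networks.
#' @examples
#' Th <- make_chain_precision(5, 0.3)
#' x1 <- mvn_sample(150, solve(Th), seed = 1)
#' x2 <- mvn_sample(150, solve(Th), seed = 2)
#' res <- nct(x1, x2, n_permutations = 50, seed = 3)
#' res$s_pvalue
#' @export
nct <- function(data1, data2, n_permutations = 1000, seed = NULL,
                pairs1 = NULL, pairs2 = NULL,
                permutation = c("auto", "pair", "plain"),
                edge_tests = TRUE, max_failure_rate = 0.05,
                gamma = 0.5, n_lambdas = 100, lambda_min_ratio = 0.01,
                skew_threshold = 1) {
  permutation <- match.arg(permutation)
  X1 <- as.matrix(data1)
  X2 <- as.matrix(data2)
  if (ncol(X1) != ncol(X2) ||
      !identical(colnames(X1), colnames(X2))) {
    stop("the two groups must have the same variables in the same order")
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  p <- ncol(X1)
  n1 <- nrow(X1)
  n2 <- nrow(X2)
  if (n1 <= p / 2 || n2 <= p / 2) {
    warning("group sizes are small relative to the number of variables")
  }
  have_pairs <- !is.null(pairs1) && !is.null(pairs2)
  if (permutation == "auto") permutation <- if (have_pairs) "pair" else "plain"
  if (permutation == "pair" && !have_pairs) {
    stop("pair permutation requires pairs1 and pairs2")
  }
  if (!is.null(seed)) set.seed(seed)

  fit_W <- function(X) .fast_network_W(X, gamma = gamma,
                                       n_lambdas = n_lambdas,
                                       lambda_min_ratio = lambda_min_ratio,
                                       skew_threshold = skew_threshold)
  W1 <- fit_W(X1)
  W2 <- fit_W(X2)
  ut <- upper.tri(W1)
  s_obs <- abs(global_strength(W1) - global_strength(W2))
  edge_diff_obs <- abs(W1 - W2)[ut]
  m_obs <- max(edge_diff_obs)

  draw <- .make_permuter(X1, X2, pairs1, pairs2, permutation)

  K <- n_permutations
  null_s <- null_m <- rep(NA_real_, K)
  E <- sum(ut)
  null_edge_ge <- if (edge_tests) integer(E) else NULL
  failures <- 0L
  for (k in seq_len(K)) {
    gs <- draw()
    Wa <- tryCatch(fit_W(gs$A), error = function(e) NULL)
    Wb <- tryCatch(fit_W(gs$B), error = function(e) NULL)
    if (is.null(Wa) || is.null(Wb)) { failures <- failures + 1L; next }
    dW <- abs(Wa - Wb)[ut]
    null_s[k] <- abs(sum(abs(Wa[ut])) - sum(abs(Wb[ut])))
    null_m[k] <- max(dW)
    if (edge_tests) null_edge_ge <- null_edge_ge + (dW >= edge_diff_obs)
  }
  if (failures > max_failure_rate * K) {
    stop(failures, " of ", K, " permutations failed to estimate")
  }
  Keff <- K - failures
  pval <- function(null, obs) (1 + sum(null >= obs, na.rm = TRUE)) / (Keff + 1)

  labels <- colnames(W1)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  idx <- which(ut, arr.ind = TRUE)
  et <- NULL
  if (edge_tests) {
    p_raw <- (1 + null_edge_ge) / (Keff + 1)
    et <- data.frame(
      node1 = labels[idx[, 1]], node2 = labels[idx[, 2]],
      w1 = W1[ut], w2 = W2[ut],
      diff = edge_diff_obs,
      p_raw = p_raw,
      p_holm = stats::p.adjust(p_raw, method = "holm"),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  structure(list(
    s_observed = s_obs, m_observed = m_obs,
    s_pvalue = pval(null_s, s_obs), m_pvalue = pval(null_m, m_obs),
    n_permutations = Keff, failures = failures,
    permutation = permutation,
    null_s = null_s[!is.na(null_s)], null_m = null_m[!is.na(null_m)],
    edge_tests = et,
    W1 = W1, W2 = W2, n1 = n1, n2 = n2
  ), class = "nct_result")
}

# Builds a closure returning permuted groups {A, B}. Pooled rows (or
# pairs) are deterministically sorted first, so the permutation stream
# does not depend on the order in which the two groups were supplied.
.make_permuter <- function(X1, X2, pairs1, pairs2, permutation) {
  if (permutation == "plain") {
    Xp <- rbind(X1, X2)
    ord <- do.call(order, as.data.frame(Xp))
    Xp <- Xp[ord, , drop = FALSE]
    n1 <- nrow(X1)
    n <- nrow(Xp)
    return(function() {
      perm <- sample.int(n)
      list(A = Xp[perm[seq_len(n1)], , drop = FALSE],
           B = Xp[perm[(n1 + 1):n], , drop = FALSE])
    })
  }
  pairs1 <- as.character(pairs1)
  pairs2 <- as.character(pairs2)
  if (length(pairs1) != nrow(X1) || length(pairs2) != nrow(X2)) {
    stop("pair identifiers must match the number of rows")
  }
  shared <- intersect(unique(pairs1), unique(pairs2))
  if (length(shared)) {
    # co-twin design: each pair split across the two groups
    if (!setequal(unique(pairs1), unique(pairs2)) ||
        anyDuplicated(pairs1) || anyDuplicated(pairs2)) {
      stop("pair-split permutation needs exactly one member of every pair per group")
    }
    ids <- sort(unique(pairs1))
    A0 <- X1[match(ids, pairs1), , drop = FALSE]
    B0 <- X2[match(ids, pairs2), , drop = FALSE]
    # canonicalize member order within each pair (lexicographic) so the
    # stream is invariant to swapping the input groups
    m <- length(ids)
    lex_greater <- function(a, b) {
      j <- which(a != b)
      length(j) > 0 && a[j[1]] > b[j[1]]
    }
    canon_swap <- vapply(seq_len(m),
                         function(i) lex_greater(A0[i, ], B0[i, ]),
                         logical(1))
    tmp <- A0[canon_swap, , drop = FALSE]
    A0[canon_swap, ] <- B0[canon_swap, , drop = FALSE]
    B0[canon_swap, ] <- tmp
    return(function() {
      sw <- stats::runif(m) < 0.5
      A <- A0
      B <- B0
      A[sw, ] <- B0[sw, , drop = FALSE]
      B[sw, ] <- A0[sw, , drop = FALSE]
      list(A = A, B = B)
    })
  }
  # pairs nested within groups: reallocate whole pairs
  if (anyNA(pairs1) || anyNA(pairs2)) stop("missing pair identifiers")
  split_pairs <- function(X, pr) {
    lapply(split(seq_len(nrow(X)), pr), function(i) X[i, , drop = FALSE])
  }
  blocks <- c(split_pairs(X1, pairs1), split_pairs(X2, pairs2))
  blocks <- blocks[order(names(blocks))]
  sizes <- vapply(blocks, nrow, integer(1))
  n1 <- nrow(X1)
  nb <- length(blocks)
  function() {
    ord <- sample.int(nb)
    csum <- cumsum(sizes[ord])
    k1 <- which(csum >= n1)[1]
    a_idx <- ord[seq_len(k1)]
    list(A = do.call(rbind, blocks[a_idx]),
         B = do.call(rbind, blocks[ord[(k1 + 1):nb]]))
  }
}

#' @export
print.nct_result <- function(x, ...) {
  cat("Network comparison test (", x$n_permutations, " permutations, ",
      x$permutation, " scheme)\n", sep = "")
  cat(sprintf("  S (global strength difference): %.4f  p = %.4f\n",
              x$s_observed, x$s_pvalue))
  cat(sprintf("  M (maximum edge difference):    %.4f  p = %.4f\n",
              x$m_observed, x$m_pvalue))
  if (!is.null(x$edge_tests)) {
    ns <- sum(x$edge_tests$p_holm < 0.05)
    cat("  edges with Holm-corrected p < 0.05: ", ns, "\n", sep = "")
  }
  invisible(x)
}

#' Per-edge invariance decisions from an NCT
#'
#' Extracts the edge-level permutation tests, optionally restricted to
#' edges incident to a set of focal nodes (the multiplicity correction is
#' then recomputed over the restricted set).
#'
#' @param result An `nct_result` fitted with `edge_tests = TRUE`.
#' @param nodes Optional character vector of focal node labels.
#' @param method Multiplicity correction (default `"holm"`).
#' @param alpha Significance level for the `significant` column.
#' @return The edge-test data frame with corrected p-values and a
#'   `significant` flag.
#' @export
edge_invariance_tests <- function(result, nodes = NULL, method = "holm",
                                  alpha = 0.05) {
  stopifnot(inherits(result, "nct_result"))
  et <- result$edge_tests
  if (is.null(et)) stop("NCT was run without edge tests")
  if (!is.null(nodes)) {
    et <- et[et$node1 %in% nodes | et$node2 %in% nodes, , drop = FALSE]
  }
  et$p_corrected <- stats::p.adjust(et$p_raw, method = method)
  et$significant <- et$p_corrected < alpha
  rownames(et) <- NULL
  et
}
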