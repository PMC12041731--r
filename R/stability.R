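#' Correlation stability (CS) coefficient by case-dropping bootstrap
#'
#' For each drop proportion q in `drop_grid`, `B` subsamples of size
#' `(1 - q) * n` are drawn without replacement, the network is
#' re-estimated with the full pipeline, and the Pearson correlation
#' between subsample and full-sample node centralities is recorded. The
#' CS-coefficient is the largest q such that at least `quantile` (default
#' 95%) of the correlations at q are `>= threshold_corr` (default 0.7),
#' with the additional requirement that all smaller q on the grid also
#' qualify. Values above 0.25 indicate acceptable stability; above 0.5,
#' good stability. The grid caps the reportable value at 0.75.
#'
#' @param data Individuals x variables matrix (raw; preprocessing happens
#'   inside each re-estimation).
#' @param measure `"strength"` or `"expected_influence"`.
#' @param B Subsamples per drop proportion (default 1000; reduce for
#'   quick diagnostics).
#' @param drop_grid Proportions of cases to drop (default 0.05 to 0.75
#'   in steps of 0.05).
#' @param threshold_corr Correlation that must be retained (default 0.7).
#' @param quantile Required fraction of qualifying subsamples (default
#'   0.95).
#' @param seed Optional integer seed.
#' @param ... Estimation settings passed on to the internal pipeline
#'   (`gamma`, `n_lambdas`, `lambda_min_ratio`, `skew_threshold`).
#' @return Object of class `stability_report`: `cs_coefficient`, `measure`,
#'   and a `grid` data frame with per-proportion mean correlation and the
#'   fraction of subsamples retaining `threshold_corr`.
#' @export
cs_coefficient <- function(data, measure = c("strength", "expected_influence"),
                           B = 1000, drop_grid = seq(0.05, 0.75, by = 0.05),
                           threshold_corr = 0.7, quantile = 0.95,
                           seed = NULL, ...) {
  measure <- match.arg(measure)
  if (B < 1) stop("B must be positive")
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(data)
  n <- nrow(X)
  fun <- if (measure == "strength") strength else expected_influence
  full <- fun(.fast_network_W(X, ...))
  ok_frac <- mean_cor <- numeric(length(drop_grid))
  for (gi in seq_along(drop_grid)) {
    q <- drop_grid[gi]
    m <- round((1 - q) * n)
    if (m <= 10) {
      warning("drop proportion ", q, " leaves too few cases; skipped")
      ok_frac[gi] <- 0
      mean_cor[gi] <- NA_real_
      next
    }
    cors <- numeric(B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, m)
      cent <- tryCatch(
        fun(.fast_network_W(X[idx, , drop = FALSE], ...)),
        error = function(e) NULL)
      cors[b] <- if (is.null(cent)) NA_real_ else
        suppressWarnings(stats::cor(cent, full))
    }
    # an all-zero (empty) subsample network gives cor = NA: count as failed
    ok_frac[gi] <- mean(!is.na(cors) & cors >= threshold_corr)
    mean_cor[gi] <- mean(cors, na.rm = TRUE)
  }
  qualifies <- ok_frac >= quantile
  cs <- 0
  for (gi in seq_along(drop_grid)) {
    if (qualifies[gi]) cs <- drop_grid[gi] else break
  }
  structure(list(
    cs_coefficient = cs, measure = measure, B = B,
    threshold_corr = threshold_corr, quantile = quantile,
    grid = data.frame(drop = drop_grid, mean_correlation = mean_cor,
                      fraction_retaining = ok_frac)
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("CS-coefficient (%s): %.2f  (B = %d, threshold %.2f)\n",
              x$measure, x$cs_coefficient, x$B, x$threshold_corr))
  invisible(x)
}

# shared worker: nonparametric case-resampling bootstrap of the upper-tri
# edge weights and node centralities; returns B x E and B x p matrices
.bootstrap_networks <- function(X, B, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  full <- estimate_network(X, return_path = FALSE, ...)
  p <- ncol(full$W)
  ut <- upper.tri(full$W)
  E <- sum(ut)
  edges <- matrix(NA_real_, B, E)
  strengths <- matrix(NA_real_, B, p)
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    Wb <- tryCatch(.fast_network_W(X[idx, , drop = FALSE], ...),
                   error = function(e) NULL)
    if (is.null(Wb)) { failures <- failures + 1L; next }
    edges[b, ] <- Wb[ut]
    strengths[b, ] <- strength(Wb)
  }
  if (failures > 0) warning(failures, " of ", B, " bootstrap re-estimations failed")
  labels <- full$labels
  pairs <- which(ut, arr.ind = TRUE)
  list(full = full, edges = edges, strengths = strengths,
       edge_names = paste(labels[pairs[, 1]], labels[pairs[, 2]], sep = "--"),
       labels = labels, failures = failures)
}

#' Bootstrap confidence intervals for edge weights
#'
#' Nonparametric case-resampling bootstrap; each resample is re-estimated
#' with the full pipeline (skew screen, nonparanormal step, EBIC-selected
#' graphical lasso). Percentile intervals at the requested level.
#'
#' @param data Individuals x variables matrix.
#' @param B Number of resamples (default 1000).
#' @param level Interval level (default 0.95).
#' @param seed Optional integer seed.
#' @param ... Passed to [estimate_network()].
#' @return Data frame, one row per unique edge: `edge`, `estimate`,
#'   `lower`, `upper`, `boot_mean`.
#' @export
edge_ci_bootstrap <- function(data, B = 1000, level = 0.95, seed = NULL, ...) {
  if (B < 1) stop("B must be positive")
  if (B == 1) warning("B = 1 gives a degenerate interval equal to the single resample")
  boot <- .bootstrap_networks(as.matrix(data), B, seed = seed, ...)
  a <- (1 - level) / 2
  qs <- apply(boot$edges, 2, stats::quantile,
              probs = c(a, 1 - a), na.rm = TRUE, names = FALSE)
  data.frame(
    edge = boot$edge_names,
    estimate = boot$full$W[upper.tri(boot$full$W)],
    lower = qs[1, ], upper = qs[2, ],
    boot_mean = colMeans(boot$edges, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Bootstrapped difference tests for edges or centralities
#'
#' For every pair of edges (or of nodes' strengths), the bootstrap
#' distribution of their difference is formed from the same resamples;
#' the pair differs significantly when the percentile interval of the
#' difference excludes zero.
#'
#' @param data Individuals x variables matrix.
#' @param B Number of resamples (default 1000).
#' @param what `"edges"` or `"centrality"` (node strength).
#' @param level Interval level (default 0.95).
#' @param seed Optional integer seed.
#' @param ... Passed to [estimate_network()].
#' @return A symmetric logical matrix: entry (a, b) is TRUE when items a
#'   and b differ significantly. Attribute `"items"` carries the labels.
#' @export
bootstrap_difference_test <- function(data, B = 1000,
                                      what = c("edges", "centrality"),
                                      level = 0.95, seed = NULL, ...) {
  what <- match.arg(what)
  boot <- .bootstrap_networks(as.matrix(data), B, seed = seed, ...)
  M <- if (what == "edges") boot$edges else boot$strengths
  items <- if (what == "edges") boot$edge_names else boot$labels
  k <- ncol(M)
  a <- (1 - level) / 2
  sig <- matrix(FALSE, k, k, dimnames = list(items, items))
  for (i in seq_len(k - 1)) {
    d <- M[, (i + 1):k, drop = FALSE] - M[, i]
    qs <- apply(d, 2, stats::quantile, probs = c(a, 1 - a),
                na.rm = TRUE, names = FALSE)
    s <- qs[1, ] > 0 | qs[2, ] < 0
    sig[i, (i + 1):k] <- s
    sig[(i + 1):k, i] <- s
  }
  attr(sig, "items") <- items
  sig
}
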