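#' Graphical lasso fit at a single penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |theta_ij|`
#' by blockwise coordinate descent. The diagonal is not penalized. Exact
#' zeros in the off-diagonal of the returned precision matrix are produced
#' by the soft-thresholding step, so the sparsity pattern is the implied
#' network.
#'
#' @param S Symmetric covariance/correlation matrix (correlation input is
#'   the standard pipeline here).
#' @param lambda Penalty, `lambda >= 0`.
#' @param maxit,tol Outer-loop iteration cap and convergence tolerance on
#'   the covariance estimate (relative to the mean |off-diagonal| of `S`).
#' @return List with `Theta` (precision), `W` (estimated covariance,
#'   `Theta^-1` at convergence) and `iters`.
#' @examples
#' S <- cov2cor(solve(make_chain_precision(5, 0.4)))
#' fit <- glasso_fit(S, lambda = 0.1)
#' @export
glasso_fit <- function(S, lambda, maxit = 200, tol = 1e-4) {
  S <- as.matrix(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    stop("S must be symmetric")
  }
  if (lambda < 0) stop("lambda must be non-negative")
  fit <- cpp_glasso(S, lambda, maxit = maxit, tol = tol)
  if (fit$iters >= maxit) {
    stop("glasso did not converge in ", maxit, " outer iterations (lambda = ",
         signif(lambda, 4), ")")
  }
  dimnames(fit$Theta) <- dimnames(S)
  fit
}

#' KKT residuals of a glasso solution
#'
#' For the penalized log-det objective the stationarity conditions are
#' `Theta^-1 - S = lambda * sign(theta_ij)` on nonzero off-diagonals and
#' `|(Theta^-1 - S)_ij| <= lambda` on zero ones. Returns the largest
#' violation, used to certify fits.
#'
#' @param Theta Fitted precision matrix.
#' @param S Input covariance/correlation matrix.
#' @param lambda Penalty used.
#' @return Maximum KKT residual (scalar, 0 for an exact solution).
#' @export
glasso_kkt <- function(Theta, S, lambda) {
  G <- solve(Theta) - S
  p <- nrow(S)
  off <- upper.tri(G) | lower.tri(G)
  zero <- off & (Theta == 0)
  nonzero <- off & (Theta != 0)
  r1 <- if (any(zero)) max(pmax(abs(G[zero]) - lambda, 0)) else 0
  r2 <- if (any(nonzero)) max(abs(G[nonzero] - lambda * sign(Theta[nonzero]))) else 0
  max(r1, r2, max(abs(diag(G))))
}

#' Precision matrix to partial-correlation weight matrix
#'
#' `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)`, with a zero diagonal:
#' the edge weights of the Gaussian graphical model.
#'
#' @param Theta Symmetric positive-definite precision matrix.
#' @return Symmetric matrix of partial correlations with `diag = 0`.
#' @export
precision_to_partial <- function(Theta) {
  d <- diag(Theta)
  if (any(d <= 0)) stop("invalid precision matrix: non-positive diagonal")
  W <- -Theta / sqrt(outer(d, d))
  diag(W) <- 0
  W
}

#' Extended Bayesian Information Criterion
#'
#' `EBIC = -2 loglik + E log(n) + 4 E gamma log(p)` where `E` is the number
#' of nonzero off-diagonal edges; `gamma = 0` recovers ordinary BIC and
#' larger `gamma` favors sparser models. Model selection picks the minimum.
#'
#' @param loglik Gaussian log-likelihood of the fitted model.
#' @param E Edge count (nonzero upper-triangle entries).
#' @param n Sample size.
#' @param p Number of variables.
#' @param gamma EBIC hyperparameter (0.5 in this pipeline's defaults).
#' @return Scalar criterion; smaller is better.
#' @export
ebic <- function(loglik, E, n, p, gamma) {
  stopifnot(E >= 0, n >= 1, p >= 1)
  -2 * loglik + E * log(n) + 4 * E * gamma * log(p)
}

#' Estimate a regularized partial-correlation network
#'
#' The full estimation pipeline: (optional) skew screening with
#' nonparanormal transformation, Pearson correlation matrix, graphical
#' lasso over a log-spaced 100-point penalty path from `lambda_max` (the
#' smallest penalty giving an empty graph) down to
#' `lambda_max * lambda_min_ratio`, EBIC at `gamma` for every model, and
#' selection of the minimizer (ties broken toward the sparser model, i.e.
#' larger penalty). Estimation uses the correlation matrix, so the result
#' is invariant to column rescaling.
#'
#' @param data Numeric matrix or data frame, individuals x variables.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambdas Number of penalty values (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest penalty
#'   (default 0.01).
#' @param preprocess Apply the skew screen + nonparanormal step first
#'   (default TRUE). Set FALSE if `data` is already preprocessed.
#' @param refit Evaluate EBIC at the support-constrained unpenalized MLE
#'   of each candidate graph and return that refit for the selected graph
#'   (default TRUE). With FALSE, EBIC uses the shrunken glasso estimates
#'   themselves, which tends to admit additional tiny spurious edges.
#' @param skew_threshold Passed to [preprocess_matrix()].
#' @param return_path Keep the full penalty path in the result (default
#'   TRUE; switched off inside permutation loops to save memory).
#' @return An object of class `network_model`: `W` (partial correlations),
#'   `Theta`, `labels`, `lambda_selected`, `ebic_value`, `gamma`, `n`,
#'   `preprocess_report`, and (optionally) `path` with per-lambda edge
#'   counts, log-likelihoods and EBIC values.
#' @examples
#' Theta <- make_chain_precision(6, 0.35)
#' X <- mvn_sample(500, solve(Theta), seed = 1)
#' fit <- estimate_network(X)
#' sum(fit$W[upper.tri(fit$W)] != 0)
#' @export
estimate_network <- function(data, gamma = 0.5, n_lambdas = 100,
                             lambda_min_ratio = 0.01, preprocess = TRUE,
                             skew_threshold = 1, return_path = TRUE,
                             refit = TRUE) {
  X <- as.matrix(data)
  if (nrow(X) <= 10) stop("need more than 10 observations")
  report <- NULL
  if (preprocess) {
    pre <- preprocess_matrix(X, threshold = skew_threshold)
    X <- pre$X
    report <- pre$report
  }
  n <- nrow(X)
  p <- ncol(X)
  S <- stats::cor(X)
  if (anyNA(S)) stop("degenerate correlation matrix (constant column?)")
  off <- abs(S[upper.tri(S)])
  lambda_max <- max(off)
  if (lambda_max < 1e-12) lambda_max <- 1e-12
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambdas))
  # EBIC selection happens inside the path fit; ties at equal EBIC go to
  # the larger lambda (sparser model) because lambdas descend
  sel <- cpp_ggm_select(S, lambdas, n, gamma, refit)
  loglik <- (n / 2) * sel$loglik_kernel
  ebics <- sel$ebic
  best <- sel$best
  Theta <- sel$Theta
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("V", seq_len(p))
  dimnames(Theta) <- list(labels, labels)
  W <- precision_to_partial(Theta)
  out <- list(
    W = W, Theta = Theta, labels = labels,
    lambda_selected = lambdas[best], ebic_value = ebics[best],
    gamma = gamma, n = n,
    preprocess_report = report
  )
  if (return_path) {
    out$path <- data.frame(lambda = lambdas, edges = as.numeric(sel$edges),
                           loglik = loglik, ebic = ebics)
  }
  class(out) <- "network_model"
  out
}

#' @export
print.network_model <- function(x, ...) {
  E <- sum(x$W[upper.tri(x$W)] != 0)
  cat("Regularized partial-correlation network\n")
  cat(sprintf("  nodes: %d   edges: %d   n: %d\n", length(x$labels), E, x$n))
  cat(sprintf("  lambda: %.4g (EBIC %.2f at gamma %.2f)\n",
              x$lambda_selected, x$ebic_value, x$gamma))
  cat(sprintf("  global strength: %.3f\n", global_strength(x$W)))
  invisible(x)
}

# Lean pipeline used inside permutation/bootstrap loops: same
# transformations as estimate_network (skew screen + nonparanormal on
# offending columns; standardization of the rest is skipped because the
# correlation matrix is scale invariant), no report, returns only W.
.fast_network_W <- function(X, gamma = 0.5, n_lambdas = 100,
                            lambda_min_ratio = 0.01, skew_threshold = 1,
                            refit = TRUE) {
  n <- nrow(X)
  X <- cpp_skew_npn(X, skew_threshold)
  S <- stats::cor(X)
  lambda_max <- max(abs(S[upper.tri(S)]), 1e-12)
  lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                     length.out = n_lambdas))
  sel <- cpp_ggm_select(S, lambdas, n, gamma, refit)
  W <- precision_to_partial(sel$Theta)
  dimnames(W) <- dimnames(S)
  W
}

#' Draw a multivariate normal sample
#'
#' Cholesky-based sampler used throughout the simulation studies.
#'
#' @param n Number of rows.
#' @param Sigma Covariance matrix.
#' @param seed Optional integer seed.
#' @return `n x p` matrix.
#' @export
mvn_sample <- function(n, Sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(Sigma)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- Z %*% chol(Sigma)
  colnames(X) <- colnames(Sigma)
  X
}
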