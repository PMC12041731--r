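# Independent reference solver for the penalized log-det objective:
# ADMM with eigendecomposition-based proximal steps. Shares no code path
# with the package's coordinate-descent glasso.
admm_glasso <- function(S, lambda, rho = 1, maxit = 5000, tol = 1e-9) {
  p <- nrow(S)
  Z <- diag(p)
  U <- matrix(0, p, p)
  Lam <- matrix(lambda, p, p)
  diag(Lam) <- 0  # unpenalized diagonal
  for (it in seq_len(maxit)) {
    eig <- eigen((Z - U) * rho - S, symmetric = TRUE)
    d <- (eig$values + sqrt(eig$values^2 + 4 * rho)) / (2 * rho)
    Theta <- eig$vectors %*% (d * t(eig$vectors))
    Zold <- Z
    A <- Theta + U
    Z <- sign(A) * pmax(abs(A) - Lam / rho, 0)
    U <- U + Theta - Z
    if (max(abs(Theta - Z)) < tol && max(abs(Z - Zold)) * rho < tol) break
  }
  (Z + t(Z)) / 2
}

# random correlation matrix with non-trivial structure
random_cor <- function(p) {
  A <- matrix(rnorm(p * p), p)
  stats::cov2cor(crossprod(A) + diag(p))
}

# upper-triangle adjacency of a weight/precision matrix
edge_set <- function(M, tol = 1e-10) {
  abs(M[upper.tri(M)]) > tol
}

# sensitivity / false positives of a recovered graph vs truth
recovery_rates <- function(W_hat, Theta_true) {
  truth <- edge_set(Theta_true)
  est <- edge_set(W_hat)
  list(sensitivity = sum(est & truth) / sum(truth),
       false_edges = sum(est & !truth))
}

# small twin configuration used across tests
test_twin_config <- function(p = 6, n_pairs = 60, boost_f = 1,
                             h2 = 0.6, c2 = 0.2, seed = 1,
                             edge = 0.3, skew = character(0)) {
  reg <- variable_registry(p = p)
  twin_config(
    n_pairs = c(MZ_F = n_pairs, DZ_F = n_pairs, MZ_M = n_pairs, DZ_M = n_pairs),
    registry = reg,
    theta_f = make_chain_precision(p, edge, boost = boost_f),
    theta_m = make_chain_precision(p, edge),
    h2 = h2, c2 = c2, skew_columns = skew, seed = seed
  )
}
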