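// Blockwise coordinate-descent graphical lasso (Friedman et al. style).
//
// Solves  max_Theta  log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |theta_ij|
// for a symmetric input matrix S (typically a correlation matrix).  The
// diagonal is not penalized, so the KKT conditions fix diag(W) = diag(S)
// for the covariance estimate W = Theta^-1.  The path driver reuses the
// previous solution (warm start) as lambda decreases, which is what makes
// 100-model EBIC paths cheap enough to re-run inside permutation loops.
//
// Implementation notes: the per-column lasso works on full p-vectors with
// the j-th coordinate pinned at zero (no submatrix copies), maintains the
// product u = W * beta incrementally, and iterates an active set between
// full sweeps, glmnet-style.  All scratch buffers live in a workspace that
// persists across the 100 path fits, so a single fit allocates nothing.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

struct GlassoWork {
  std::vector<uvec> others;  // per column: all indices except the column
  vec beta, u;
  uvec active;
  mat cholbuf;
  explicit GlassoWork(uword p)
      : others(p), beta(p), u(p), active(p), cholbuf(p, p) {
    for (uword j = 0; j < p; ++j) {
      uvec o(p > 1 ? p - 1 : 1);
      uword k = 0;
      for (uword i = 0; i < p; ++i) if (i != j) o(k++) = i;
      others[j] = o;
    }
  }
};

// One pass of coordinate descent over the coordinates in `set` (all != j).
// beta(j) stays 0.  u = W * beta is maintained with hand-rolled loops (the
// vectors are tiny, so BLAS dispatch would dominate).  Returns max |change|.
static double cd_pass(const mat& W, const double* scol, double* beta,
                      double* u, double lambda, const uvec& set) {
  const uword p = W.n_rows;
  double maxdiff = 0.0;
  for (uword t = 0; t < set.n_elem; ++t) {
    const uword k = set(t);
    const double* wcol = W.colptr(k);
    const double bk_old = beta[k];
    const double grad = scol[k] - (u[k] - wcol[k] * bk_old);
    const double bk_new = soft(grad, lambda) / wcol[k];
    if (bk_new != bk_old) {
      const double d = bk_new - bk_old;
      beta[k] = bk_new;
      for (uword i = 0; i < p; ++i) u[i] += wcol[i] * d;
      const double ad = std::abs(d);
      if (ad > maxdiff) maxdiff = ad;
    }
  }
  return maxdiff;
}

// u = W * beta exploiting sparsity of beta
static void sparse_wbeta(const mat& W, const double* beta, double* u) {
  const uword p = W.n_rows;
  for (uword i = 0; i < p; ++i) u[i] = 0.0;
  for (uword k = 0; k < p; ++k) {
    const double bk = beta[k];
    if (bk != 0.0) {
      const double* wcol = W.colptr(k);
      for (uword i = 0; i < p; ++i) u[i] += wcol[i] * bk;
    }
  }
}

// Lasso subproblem for column j: min 0.5 b'W11 b - s12'b + lambda |b|_1,
// warm-started at beta (full p-vector, beta(j) == 0).
static void lasso_col(const mat& W, const double* scol, double* beta,
                      double* u, double lambda, uword j, GlassoWork& wk,
                      int maxit, double tol) {
  const uword p = W.n_rows;
  sparse_wbeta(W, beta, u);
  if (cd_pass(W, scol, beta, u, lambda, wk.others[j]) < tol) return;
  for (int it = 0; it < maxit; ++it) {
    uword na = 0;
    for (uword k = 0; k < p; ++k)
      if (k != j && beta[k] != 0.0) wk.active(na++) = k;
    for (int it2 = 0; it2 < maxit; ++it2) {
      if (cd_pass(W, scol, beta, u, lambda, wk.active.head(na)) < tol) break;
    }
    if (cd_pass(W, scol, beta, u, lambda, wk.others[j]) < tol) break;
  }
}

static double mean_abs_offdiag(const mat& S) {
  const uword p = S.n_rows;
  if (p < 2) return 1.0;
  double sbar = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) sbar += std::abs(S(i, j));
  return sbar / (0.5 * double(p) * double(p - 1));
}

// recover Theta from W and the regression coefficients
static void recover_theta(const mat& S, const mat& W, const mat& Bfull,
                          mat& Theta) {
  const uword p = S.n_rows;
  for (uword j = 0; j < p; ++j) {
    double dotwb = dot(W.col(j), Bfull.col(j));  // Bfull(j, j) == 0
    double tjj = 1.0 / (W(j, j) - dotwb);
    Theta(j, j) = tjj;
    for (uword i = 0; i < p; ++i)
      if (i != j) Theta(i, j) = -Bfull(i, j) * tjj;
  }
  // symmetrize round-off; keep exact zeros only where both halves are zero
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) {
      double a = Theta(i, j), b = Theta(j, i);
      double v = (a == 0.0 || b == 0.0) ? 0.0 : 0.5 * (a + b);
      Theta(i, j) = v;
      Theta(j, i) = v;
    }
}

// One glasso fit.  W and Bfull (p x p, zero diagonal) carry warm starts.
static int glasso_core(const mat& S, double lambda, mat& W, mat& Bfull,
                       mat& Theta, GlassoWork& wk, int maxit, double tol,
                       int inner_maxit, double inner_tol) {
  const uword p = S.n_rows;
  if (p == 1) {
    W(0, 0) = S(0, 0);
    Theta(0, 0) = 1.0 / S(0, 0);
    return 0;
  }
  double thr = tol * std::max(mean_abs_offdiag(S), 1e-10);
  W.diag() = S.diag();
  int it = 0;
  for (; it < maxit; ++it) {
    double maxchange = 0.0;
    for (uword j = 0; j < p; ++j) {
      double* bcol = Bfull.colptr(j);
      double* ubuf = wk.u.memptr();
      lasso_col(W, S.colptr(j), bcol, ubuf, lambda, j, wk,
                inner_maxit, inner_tol);
      // new column of W: w12 = W11 * beta = (W * beta) restricted off j
      for (uword i = 0; i < p; ++i) {
        if (i == j) continue;
        double d = std::abs(W(i, j) - ubuf[i]);
        if (d > maxchange) maxchange = d;
        W(i, j) = ubuf[i];
        W(j, i) = ubuf[i];
      }
    }
    if (maxchange < thr) { ++it; break; }
  }
  recover_theta(S, W, Bfull, Theta);
  return it;
}

// Support-constrained Gaussian MLE: maximize log det Theta - tr(S Theta)
// subject to theta_ij = 0 off the given support (supp[j] lists the allowed
// partners of column j).  Same blockwise scheme with lambda = 0.
static void constrained_mle(const mat& S, const std::vector<uvec>& supp,
                            mat& W, mat& Bfull, mat& Theta, GlassoWork& wk,
                            int maxit, double tol,
                            int inner_maxit, double inner_tol) {
  const uword p = S.n_rows;
  double thr = tol * std::max(mean_abs_offdiag(S), 1e-10);
  W.diag() = S.diag();
  for (int it = 0; it < maxit; ++it) {
    double maxchange = 0.0;
    for (uword j = 0; j < p; ++j) {
      double* bcol = Bfull.colptr(j);
      double* ubuf = wk.u.memptr();
      sparse_wbeta(W, bcol, ubuf);
      if (supp[j].n_elem > 0) {
        for (int it2 = 0; it2 < inner_maxit; ++it2) {
          if (cd_pass(W, S.colptr(j), bcol, ubuf, 0.0, supp[j]) < inner_tol)
            break;
        }
      }
      for (uword i = 0; i < p; ++i) {
        if (i == j) continue;
        double d = std::abs(W(i, j) - ubuf[i]);
        if (d > maxchange) maxchange = d;
        W(i, j) = ubuf[i];
        W(j, i) = ubuf[i];
      }
    }
    if (maxchange < thr) break;
  }
  recover_theta(S, W, Bfull, Theta);
}

// log det of an SPD matrix via in-place Cholesky on a reusable buffer
static double chol_logdet(const mat& A, mat& buf) {
  const uword p = A.n_rows;
  buf = A;
  double ld = 0.0;
  for (uword j = 0; j < p; ++j) {
    double d = buf(j, j);
    for (uword k = 0; k < j; ++k) d -= buf(j, k) * buf(j, k);
    if (d <= 0.0) return -datum::inf;
    double l = std::sqrt(d);
    buf(j, j) = l;
    ld += std::log(l);
    for (uword i = j + 1; i < p; ++i) {
      double s = buf(i, j);
      for (uword k = 0; k < j; ++k) s -= buf(i, k) * buf(j, k);
      buf(i, j) = s / l;
    }
  }
  return 2.0 * ld;
}

// [[Rcpp::export]]
Rcpp::List cpp_glasso(const arma::mat& S, double lambda,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W0 = R_NilValue,
                      int maxit = 200, double tol = 1e-4,
                      int inner_maxit = 500, double inner_tol = 1e-6) {
  const uword p = S.n_rows;
  mat W = W0.isNotNull() ? mat(Rcpp::as<mat>(W0.get())) : mat(S);
  mat Bfull(p, p, fill::zeros);
  mat Theta(p, p, fill::zeros);
  GlassoWork wk(p);
  int iters = glasso_core(S, lambda, W, Bfull, Theta, wk, maxit, tol,
                          inner_maxit, inner_tol);
  return Rcpp::List::create(Rcpp::Named("Theta") = Theta,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("iters") = iters);
}

// Path + EBIC selection in one call: fits the descending-lambda path with
// warm starts and computes EBIC(k) = -2 l(k) + E log n + 4 E gamma log p
// per model, where by default (refit = true, the Foygel-Drton convention)
// the log-likelihood l is evaluated at the support-constrained unpenalized
// MLE of each model's graph rather than at the shrunken glasso estimate;
// consecutive lambdas sharing a support reuse the refit.  Returns the
// selected precision matrix (ties broken toward the first, i.e. largest,
// lambda) plus per-lambda summaries.
// [[Rcpp::export]]
Rcpp::List cpp_ggm_select(const arma::mat& S, const arma::vec& lambdas,
                          double n, double gamma, bool refit = true,
                          int maxit = 200, double tol = 1e-4,
                          int inner_maxit = 500, double inner_tol = 1e-6) {
  const uword p = S.n_rows;
  const uword K = lambdas.n_elem;
  vec edges(K), llkern(K), ebics(K);
  mat W = S;
  mat Bfull(p, p, fill::zeros);
  mat Theta(p, p, fill::zeros);
  mat Wr = S, Br(p, p, fill::zeros), Theta_r(p, p, fill::zeros);
  GlassoWork wk(p);
  std::vector<uvec> supp(p);
  std::vector<std::vector<unsigned char> > scur(p), sprev(p);
  for (uword j = 0; j < p; ++j) {
    scur[j].assign(p, 0);
    sprev[j].assign(p, 1);  // force a refit at the first lambda
  }
  bool have_prev = false;
  double prev_ll = 0.0;
  long total_iters = 0;
  long n_refits = 0;
  mat best_Theta(p, p, fill::zeros);
  double best_ebic = datum::inf;
  uword best_k = 0;
  const double logn = std::log(n), logp = std::log(double(p));
  for (uword k = 0; k < K; ++k) {
    total_iters += glasso_core(S, lambdas(k), W, Bfull, Theta, wk, maxit,
                               tol, inner_maxit, inner_tol);
    double E = 0.0;
    bool changed = !have_prev;
    for (uword j = 0; j < p; ++j) {
      for (uword i = 0; i < p; ++i) {
        unsigned char on = (i != j) && (std::abs(Theta(i, j)) > 1e-10);
        scur[j][i] = on;
        if (on && i < j) E += 1.0;
        if (on != sprev[j][i]) changed = true;
      }
    }
    edges(k) = E;
    const mat* Tuse = &Theta;
    if (refit) {
      if (!changed) {
        llkern(k) = prev_ll;
        ebics(k) = -n * llkern(k) + E * logn + 4.0 * E * gamma * logp;
        continue;  // same support, same refit: cannot beat the stored best
      }
      for (uword j = 0; j < p; ++j) {
        uvec s(p);
        uword m = 0;
        for (uword i = 0; i < p; ++i) if (scur[j][i]) s(m++) = i;
        supp[j] = s.head(m);
        for (uword i = 0; i < p; ++i)
          if (i != j && !scur[j][i]) Br(i, j) = 0.0;
        std::swap(sprev[j], scur[j]);
      }
      have_prev = true;
      ++n_refits;
      constrained_mle(S, supp, Wr, Br, Theta_r, wk, maxit, tol,
                      inner_maxit, inner_tol);
      Tuse = &Theta_r;
    }
    double ld = chol_logdet(*Tuse, wk.cholbuf);
    llkern(k) = ld - accu(S % (*Tuse));
    prev_ll = llkern(k);
    ebics(k) = -n * llkern(k) + E * logn + 4.0 * E * gamma * logp;
    if (ebics(k) < best_ebic - 1e-9) {
      best_ebic = ebics(k);
      best_k = k;
      best_Theta = *Tuse;
    }
  }
  return Rcpp::List::create(Rcpp::Named("Theta") = best_Theta,
                            Rcpp::Named("best") = best_k + 1,
                            Rcpp::Named("edges") = edges,
                            Rcpp::Named("loglik_kernel") = llkern,
                            Rcpp::Named("ebic") = ebics,
                            Rcpp::Named("iterations") = total_iters,
                            Rcpp::Named("refits") = n_refits);
}

// Skew screen + nonparanormal transform, mirroring the R reference
// implementation exactly: columns with |g1 skewness| > threshold are
// replaced by qnorm of the Winsorized empirical CDF of their average
// ranks, rescaled to unit sample variance.  Used by the lean pipeline
// inside permutation loops.
// [[Rcpp::export]]
arma::mat cpp_skew_npn(const arma::mat& X, double threshold) {
  const uword n = X.n_rows, p = X.n_cols;
  mat out = X;
  const double delta = 1.0 / (4.0 * std::pow(double(n), 0.25) *
                              std::sqrt(datum::pi * std::log(double(n))));
  vec r(n);
  for (uword j = 0; j < p; ++j) {
    const double* x = X.colptr(j);
    double m = 0.0;
    for (uword i = 0; i < n; ++i) m += x[i];
    m /= double(n);
    double m2 = 0.0, m3 = 0.0;
    for (uword i = 0; i < n; ++i) {
      const double c = x[i] - m;
      m2 += c * c;
      m3 += c * c * c;
    }
    m2 /= double(n);
    m3 /= double(n);
    if (m2 <= 0.0) Rcpp::stop("constant column");
    if (std::abs(m3 / std::pow(m2, 1.5)) <= threshold) continue;
    // average ranks via sort order
    uvec ord = sort_index(X.col(j));
    uword i = 0;
    while (i < n) {
      uword k = i;
      while (k + 1 < n && x[ord(k + 1)] == x[ord(i)]) ++k;
      const double avg = 0.5 * (double(i) + double(k)) + 1.0;
      for (uword t = i; t <= k; ++t) r(ord(t)) = avg;
      i = k + 1;
    }
    double zm = 0.0;
    double* o = out.colptr(j);
    for (uword t = 0; t < n; ++t) {
      double u = r(t) / double(n);
      if (u < delta) u = delta;
      if (u > 1.0 - delta) u = 1.0 - delta;
      o[t] = R::qnorm5(u, 0.0, 1.0, 1, 0);
      zm += o[t];
    }
    zm /= double(n);
    double zv = 0.0;
    for (uword t = 0; t < n; ++t) zv += (o[t] - zm) * (o[t] - zm);
    const double sdz = std::sqrt(zv / double(n - 1));
    for (uword t = 0; t < n; ++t) o[t] /= sdz;
  }
  return out;
}

// Fit a whole descending-lambda path with warm starts.
// Returns the Theta cube (p x p x K), per-lambda edge counts, and the
// log-likelihood kernel log det(Theta) - tr(S Theta) (scaled by n/2 in R).
// [[Rcpp::export]]
Rcpp::List cpp_glasso_path(const arma::mat& S, const arma::vec& lambdas,
                           int maxit = 200, double tol = 1e-4,
                           int inner_maxit = 500, double inner_tol = 1e-6) {
  const uword p = S.n_rows;
  const uword K = lambdas.n_elem;
  cube Thetas(p, p, K);
  vec edges(K), llkern(K);
  mat W = S;
  mat Bfull(p, p, fill::zeros);
  mat Theta(p, p, fill::zeros);
  GlassoWork wk(p);
  for (uword k = 0; k < K; ++k) {
    glasso_core(S, lambdas(k), W, Bfull, Theta, wk, maxit, tol,
                inner_maxit, inner_tol);
    Thetas.slice(k) = Theta;
    double E = 0.0;
    for (uword i = 0; i < p; ++i)
      for (uword j = i + 1; j < p; ++j)
        if (std::abs(Theta(i, j)) > 1e-10) E += 1.0;
    edges(k) = E;
    llkern(k) = chol_logdet(Theta, wk.cholbuf) - accu(S % Theta);
  }
  return Rcpp::List::create(Rcpp::Named("Thetas") = Thetas,
                            Rcpp::Named("edges") = edges,
                            Rcpp::Named("loglik_kernel") = llkern);
}
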