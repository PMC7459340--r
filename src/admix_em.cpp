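#include <Rcpp.h>
using namespace Rcpp;

// EM for the unsupervised admixture model:
//   g_ij ~ Binomial(2, pi_ij),  pi_ij = sum_k q_ik f_kj
// Block EM updates (responsibilities a/b for ALT/REF allele copies):
//   q_ik <- sum_j [ g a_ijk + (2-g) b_ijk ] / (2 M_i)
//   f_kj <- sum_i g a_ijk / sum_i [ g a_ijk + (2-g) b_ijk ]
// Missing genotypes are coded -1 and skipped everywhere.
// Returns Q, F, the per-iteration log-likelihood trace (computed at the
// parameters entering each iteration, hence monotone), and a convergence
// flag on |delta loglik| < tol.
// [[Rcpp::export]]
List admix_em_cpp(IntegerMatrix G, NumericMatrix Q0, NumericMatrix F0,
                  int max_iter, double tol) {
  const int n = G.nrow(), L = G.ncol(), K = Q0.nrow() == 0 ? 0 : Q0.ncol();
  NumericMatrix Q(clone(Q0)), F(clone(F0));
  std::vector<double> ll_trace;
  ll_trace.reserve(max_iter);
  const double fmin = 1e-6, fmax = 1.0 - 1e-6;

  // per-sample non-missing counts
  std::vector<int> M(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j)
      if (G(i, j) >= 0) ++M[i];

  NumericMatrix Qnum(n, K), Fnum(K, L), Fden(K, L);
  bool converged = false;
  double ll_prev = R_NegInf;

  for (int it = 0; it < max_iter; ++it) {
    std::fill(Qnum.begin(), Qnum.end(), 0.0);
    std::fill(Fnum.begin(), Fnum.end(), 0.0);
    std::fill(Fden.begin(), Fden.end(), 0.0);
    double ll = 0.0;

    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < n; ++i) {
        const int g = G(i, j);
        if (g < 0) continue;
        double pi = 0.0;
        for (int k = 0; k < K; ++k) pi += Q(i, k) * F(k, j);
        if (pi < fmin) pi = fmin;
        if (pi > fmax) pi = fmax;
        ll += g * std::log(pi) + (2 - g) * std::log(1.0 - pi);
        const double inv_pi = 1.0 / pi, inv_qi = 1.0 / (1.0 - pi);
        for (int k = 0; k < K; ++k) {
          const double a = Q(i, k) * F(k, j) * inv_pi;          // ALT resp.
          const double b = Q(i, k) * (1.0 - F(k, j)) * inv_qi;  // REF resp.
          const double ga = g * a, gb = (2 - g) * b;
          Qnum(i, k) += ga + gb;
          Fnum(k, j) += ga;
          Fden(k, j) += ga + gb;
        }
      }
    }
    ll_trace.push_back(ll);

    // M-step
    for (int i = 0; i < n; ++i) {
      if (M[i] == 0) continue;
      const double denom = 2.0 * M[i];
      for (int k = 0; k < K; ++k) Q(i, k) = Qnum(i, k) / denom;
    }
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < L; ++j) {
        double f = Fden(k, j) > 0 ? Fnum(k, j) / Fden(k, j) : F(k, j);
        if (f < fmin) f = fmin;
        if (f > fmax) f = fmax;
        F(k, j) = f;
      }

    if (it > 0 && std::abs(ll - ll_prev) < tol) {
      converged = true;
      break;
    }
    ll_prev = ll;
  }

  return List::create(_["Q"] = Q, _["F"] = F,
                      _["loglik"] = NumericVector(ll_trace.begin(),
                                                  ll_trace.end()),
                      _["converged"] = converged);
}

// Held-out mean binomial deviance of masked entries given Q and F:
//   -[ g log(pi) + (2-g) log(1-pi) ] / 2 averaged over entries.
// [[Rcpp::export]]
double admix_heldout_deviance_cpp(IntegerMatrix G, NumericMatrix Q,
                                  NumericMatrix F, IntegerMatrix mask_idx) {
  const int K = Q.ncol();
  const int m = mask_idx.nrow();
  double dev = 0.0;
  for (int r = 0; r < m; ++r) {
    const int i = mask_idx(r, 0) - 1, j = mask_idx(r, 1) - 1;
    const int g = G(i, j);
    double pi = 0.0;
    for (int k = 0; k < K; ++k) pi += Q(i, k) * F(k, j);
    if (pi < 1e-6) pi = 1e-6;
    if (pi > 1.0 - 1e-6) pi = 1.0 - 1e-6;
    dev += -(g * std::log(pi) + (2 - g) * std::log(1.0 - pi)) / 2.0;
  }
  return m > 0 ? dev / m : NA_REAL;
}
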