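#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Second-order Volterra expansion of the reference history h (current
// sample first): the memory+1 linear lags followed by all distinct
// pairwise products h[p]*h[q], p <= q, in row-major order. Must stay in
// step with volterra_expand() on the R side.
static void expand_history(const arma::vec& h, bool second_order,
                           arma::vec& phi) {
  const arma::uword m1 = h.n_elem;
  arma::uword idx = 0;
  for (arma::uword i = 0; i < m1; ++i) phi[idx++] = h[i];
  if (second_order) {
    for (arma::uword p = 0; p < m1; ++p)
      for (arma::uword q = p; q < m1; ++q)
        phi[idx++] = h[p] * h[q];
  }
}

// Exponentially-weighted RLS over the Volterra expansion of the reference.
// A-posteriori residual: s_hat(k) = x(k) - w(k)' phi(k) with w(k) already
// updated on sample k, matching the closed-form weighted least-squares
// coefficient vector at sample k.
// [[Rcpp::export]]
Rcpp::List rls_core(const arma::vec& x, const arma::vec& a, int memory,
                    double lambda, double init_diag, bool second_order) {
  const arma::uword M = x.n_elem;
  if (a.n_elem != M) Rcpp::stop("x and a must have equal length");
  if (!(lambda > 0.0 && lambda <= 1.0)) Rcpp::stop("lambda must be in (0,1]");
  if (!x.is_finite() || !a.is_finite())
    Rcpp::stop("numeric error: non-finite input");
  const arma::uword m1 = memory + 1;
  const arma::uword D = second_order ? m1 + m1 * (m1 + 1) / 2 : m1;

  arma::vec w(D, arma::fill::zeros);
  arma::mat P(D, D, arma::fill::eye);
  P *= init_diag;
  arma::vec s_hat(M), phi(D), h(m1), Pphi(D), g(D);

  for (arma::uword k = 0; k < M; ++k) {
    for (arma::uword j = 0; j < m1; ++j)
      h[j] = (k >= j) ? a[k - j] : 0.0;  // zero-padded history
    expand_history(h, second_order, phi);
    Pphi = P * phi;
    const double denom = lambda + arma::dot(phi, Pphi);
    g = Pphi / denom;
    const double e = x[k] - arma::dot(w, phi);
    w += g * e;
    P = (P - g * Pphi.t()) / lambda;
    P = 0.5 * (P + P.t());
    s_hat[k] = x[k] - arma::dot(w, phi);
  }
  return Rcpp::List::create(Rcpp::Named("s_hat") = s_hat,
                            Rcpp::Named("w") = w,
                            Rcpp::Named("D") = (double)D);
}
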