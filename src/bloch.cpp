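// Bloch-McConnell propagators for N-site chemical exchange.
//
// Basis for CEST: per state s the components (Mx, My, Mz), plus one constant
// element carrying the R1*Meq inflow, so the inhomogeneous equations become a
// single linear system propagated exactly with a matrix exponential.
// For CPMG only in-phase transverse magnetization is evolved (complex M+ per
// state); 180-degree pulses are ideal and act as complex conjugation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double TWO_PI = 6.283185307179586476925287;

// CEST saturation profile for every state at once.
// K is the S x S first-order rate matrix (off-diagonal K[j,i] = k_{i->j},
// columns sum to zero, K %*% pops = 0).
// Returns an S x n matrix of I/I0 = Mz_s(Tex) / p_s for each offset.
// [[Rcpp::export]]
arma::mat bm_cest(const arma::vec& pops,
                  const arma::vec& R1,
                  const arma::vec& R2,
                  const arma::vec& shifts_ppm,
                  double larmor_MHz,
                  const arma::vec& offsets_ppm,
                  double B1_Hz,
                  double Tex_s,
                  const arma::mat& K) {
  const arma::uword S = pops.n_elem;
  const arma::uword n = offsets_ppm.n_elem;
  const arma::uword dim = 3 * S + 1;
  const double w1 = TWO_PI * B1_Hz;

  arma::mat out(S, n);
  arma::vec m0(dim, arma::fill::zeros);
  for (arma::uword s = 0; s < S; ++s) m0(3 * s + 2) = pops(s);
  m0(dim - 1) = 1.0;

  arma::mat L(dim, dim);
  for (arma::uword k = 0; k < n; ++k) {
    L.zeros();
    for (arma::uword s = 0; s < S; ++s) {
      const double dw = TWO_PI * larmor_MHz * (shifts_ppm(s) - offsets_ppm(k));
      const arma::uword x = 3 * s, y = 3 * s + 1, z = 3 * s + 2;
      L(x, x) = -R2(s);  L(x, y) =  dw;
      L(y, x) = -dw;     L(y, y) = -R2(s);  L(y, z) = w1;
      L(z, y) = -w1;     L(z, z) = -R1(s);
      L(z, dim - 1) = R1(s) * pops(s);
      for (arma::uword t = 0; t < S; ++t) {
        for (arma::uword c = 0; c < 3; ++c) L(3 * s + c, 3 * t + c) += K(s, t);
      }
    }
    arma::vec m = arma::expmat(L * Tex_s) * m0;
    for (arma::uword s = 0; s < S; ++s) {
      out(s, k) = (pops(s) > 0.0) ? m(3 * s + 2) / pops(s) : 0.0;
    }
  }
  return out;
}

// Constant-time CPMG echo train with ideal instantaneous 180 pulses.
// necho(k) = n for nu(k); the train is [tau-180-tau]^(2n), tau = Tcp/(4n).
// M+(0) carries the equilibrium populations; R2eff per observed state s is
// -(1/Tcp) * log(|M_s(Tcp)| / p_s). Returns S x n.
// [[Rcpp::export]]
arma::mat bm_cpmg(const arma::vec& pops,
                  const arma::vec& R2,
                  const arma::vec& shifts_ppm,
                  double larmor_MHz,
                  const arma::ivec& necho,
                  double Tcp,
                  const arma::mat& K) {
  const arma::uword S = pops.n_elem;
  const arma::uword n = necho.n_elem;
  arma::mat out(S, n);

  arma::cx_mat A(S, S);
  const arma::cx_double I(0.0, 1.0);
  for (arma::uword k = 0; k < n; ++k) {
    const int ne = necho(k);
    const double tau = Tcp / (4.0 * ne);
    A.zeros();
    for (arma::uword s = 0; s < S; ++s) {
      // offsets relative to the first state: a common offset is a global
      // phase and does not change |M|
      const double dw = TWO_PI * larmor_MHz * (shifts_ppm(s) - shifts_ppm(0));
      A(s, s) = arma::cx_double(-R2(s), dw);
      for (arma::uword t = 0; t < S; ++t) A(s, t) += K(s, t);
    }
    const arma::cx_mat P = arma::expmat(A * tau);
    arma::cx_vec m = arma::conv_to<arma::cx_vec>::from(pops);
    for (int e = 0; e < 2 * ne; ++e) {
      m = P * m;
      m = arma::conj(m);
      m = P * m;
    }
    for (arma::uword s = 0; s < S; ++s) {
      out(s, k) = (pops(s) > 0.0)
        ? -std::log(std::abs(m(s)) / pops(s)) / Tcp
        : NA_REAL;
    }
  }
  return out;
}
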