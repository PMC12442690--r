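// Overdamped Langevin (Euler-Maruyama) integrator for the coarse-grained
// Go-like bead model, with optional ratchet-and-pawl biasing along the
// contact-map collective variable:
//   rho(t)   = (CV(t) - CV_target)^2
//   rho_m(t) = running minimum of rho
//   V_bias   = kappa/2 * (rho - rho_m)^2   when rho > rho_m, else 0
// Random numbers come from R's RNG (set.seed-reproducible).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Rational switching function C(x) = (1 - x^6)/(1 - x^10) evaluated in the
// factored geometric-series form (sum x^k, k<6)/(sum x^k, k<10), which is
// finite and smooth at x = 1 (value 0.6).
static inline double cfun(double x) {
  double num = 0.0, den = 0.0, p = 1.0;
  for (int k = 0; k < 10; ++k) {
    if (k < 6) num += p;
    den += p;
    p *= x;
  }
  return num / den;
}

// dC/dx from the factored form.
static inline double cfun_d(double x) {
  double num = 0.0, den = 0.0, dnum = 0.0, dden = 0.0;
  for (int k = 0; k < 10; ++k) {
    const double xk = std::pow(x, k);
    const double dxk = (k == 0) ? 0.0 : k * std::pow(x, k - 1);
    if (k < 6) { num += xk; dnum += dxk; }
    den += xk; dden += dxk;
  }
  return (dnum * den - num * dden) / (den * den);
}

// [[Rcpp::export]]
double contact_switch_cpp(double r, double r0) {
  return cfun(r / r0);
}

// [[Rcpp::export]]
Rcpp::NumericVector contact_switch_vec_cpp(const Rcpp::NumericVector& r, double r0) {
  Rcpp::NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = cfun(r[i] / r0);
  return out;
}

struct PairForces {
  double energy;
  double cv;
};

// Potential energy of the toy model (no bias).
// [[Rcpp::export]]
double toy_energy_cpp(const arma::mat& x,
                      const arma::imat& bonds, const arma::vec& bond_r0, double kbond,
                      const arma::imat& natpairs, const arma::vec& nat_sigma, double eps_nat,
                      const arma::imat& reppairs, double rep_sigma, double eps_rep) {
  double E = 0.0;
  for (arma::uword b = 0; b < bonds.n_rows; ++b) {
    const arma::rowvec d = x.row(bonds(b, 0)) - x.row(bonds(b, 1));
    const double r = arma::norm(d);
    E += 0.5 * kbond * (r - bond_r0(b)) * (r - bond_r0(b));
  }
  for (arma::uword p = 0; p < natpairs.n_rows; ++p) {
    const arma::rowvec d = x.row(natpairs(p, 0)) - x.row(natpairs(p, 1));
    const double r = arma::norm(d);
    const double sr = nat_sigma(p) / r;
    const double sr2 = sr * sr;
    const double sr10 = sr2 * sr2 * sr2 * sr2 * sr2;
    const double sr12 = sr10 * sr2;
    E += eps_nat * (5.0 * sr12 - 6.0 * sr10);
  }
  for (arma::uword p = 0; p < reppairs.n_rows; ++p) {
    const arma::rowvec d = x.row(reppairs(p, 0)) - x.row(reppairs(p, 1));
    const double r = arma::norm(d);
    const double sr = rep_sigma / r;
    const double sr2 = sr * sr;
    const double sr12 = sr2 * sr2 * sr2 * sr2 * sr2 * sr2;
    E += eps_rep * sr12;
  }
  return E;
}

// [[Rcpp::export]]
Rcpp::List langevin_rmd_cpp(const arma::mat& x0,
                            const arma::imat& bonds, const arma::vec& bond_r0, double kbond,
                            const arma::imat& natpairs, const arma::vec& nat_sigma, double eps_nat,
                            const arma::imat& reppairs, double rep_sigma, double eps_rep,
                            const arma::imat& cvpairs, const arma::vec& cv_cnat, double cv_r0,
                            const arma::imat& qpairs, const arma::vec& q_r0,
                            double q_beta, double q_lambda,
                            double dt, double gamma, double kT,
                            int nsteps, int save_every,
                            bool bias_on, double kappa, double cv_target,
                            double blow_threshold) {
  const arma::uword n = x0.n_rows;
  arma::mat x = x0;
  arma::mat F(n, 3);

  const int nsave = nsteps / save_every + 1;
  arma::cube frames(n, 3, nsave);
  arma::mat series(nsave, 6);  // step, Q, CV, rho, rho_m, bias energy
  int isave = 0;

  double rho_m = R_PosInf;
  bool ok = true;
  const double noise_scale = std::sqrt(2.0 * kT * dt / gamma);

  auto compute_cv = [&](const arma::mat& xx) {
    double cv = 0.0;
    for (arma::uword p = 0; p < cvpairs.n_rows; ++p) {
      const double r = arma::norm(xx.row(cvpairs(p, 0)) - xx.row(cvpairs(p, 1)));
      const double d = cfun(r / cv_r0) - cv_cnat(p);
      cv += d * d;
    }
    return cv;
  };
  auto compute_q = [&](const arma::mat& xx) {
    if (qpairs.n_rows == 0) return NA_REAL;
    double q = 0.0;
    for (arma::uword p = 0; p < qpairs.n_rows; ++p) {
      const double r = arma::norm(xx.row(qpairs(p, 0)) - xx.row(qpairs(p, 1)));
      q += 1.0 / (1.0 + std::exp(q_beta * (r - q_lambda * q_r0(p))));
    }
    return q / qpairs.n_rows;
  };

  for (int step = 0; step <= nsteps; ++step) {
    // conservative forces
    F.zeros();
    for (arma::uword b = 0; b < bonds.n_rows; ++b) {
      const int i = bonds(b, 0), j = bonds(b, 1);
      const arma::rowvec d = x.row(i) - x.row(j);
      const double r = arma::norm(d);
      const arma::rowvec f = -kbond * (r - bond_r0(b)) / r * d;
      F.row(i) += f;
      F.row(j) -= f;
    }
    for (arma::uword p = 0; p < natpairs.n_rows; ++p) {
      const int i = natpairs(p, 0), j = natpairs(p, 1);
      const arma::rowvec d = x.row(i) - x.row(j);
      const double r = arma::norm(d);
      const double sr = nat_sigma(p) / r;
      const double sr2 = sr * sr;
      const double sr10 = sr2 * sr2 * sr2 * sr2 * sr2;
      const double sr12 = sr10 * sr2;
      // dV/dr = 60*eps*(sr10 - sr12)/r ; F_i = -dV/dr * rhat
      const double fmag = eps_nat * 60.0 * (sr10 - sr12) / r;
      const arma::rowvec f = -fmag / r * d;
      F.row(i) += f;
      F.row(j) -= f;
    }
    for (arma::uword p = 0; p < reppairs.n_rows; ++p) {
      const int i = reppairs(p, 0), j = reppairs(p, 1);
      const arma::rowvec d = x.row(i) - x.row(j);
      const double r = arma::norm(d);
      const double sr = rep_sigma / r;
      const double sr2 = sr * sr;
      const double sr12 = sr2 * sr2 * sr2 * sr2 * sr2 * sr2;
      const double fmag = -12.0 * eps_rep * sr12 / r;  // dV/dr
      const arma::rowvec f = -fmag / r * d;
      F.row(i) += f;
      F.row(j) -= f;
    }

    // ratchet-and-pawl bias
    const double cv = compute_cv(x);
    const double rho = (cv - cv_target) * (cv - cv_target);
    double ebias = 0.0;
    if (bias_on) {
      if (rho < rho_m) rho_m = rho;
      if (rho > rho_m && kappa > 0.0) {
        ebias = 0.5 * kappa * (rho - rho_m) * (rho - rho_m);
        const double pref = -kappa * (rho - rho_m) * 2.0 * (cv - cv_target);
        for (arma::uword p = 0; p < cvpairs.n_rows; ++p) {
          const int i = cvpairs(p, 0), j = cvpairs(p, 1);
          const arma::rowvec d = x.row(i) - x.row(j);
          const double r = arma::norm(d);
          const double dC = cfun_d(r / cv_r0) / cv_r0;
          const double dcv_dr = 2.0 * (cfun(r / cv_r0) - cv_cnat(p)) * dC;
          const arma::rowvec f = pref * dcv_dr / r * d;
          F.row(i) += f;
          F.row(j) -= f;
        }
      }
    }

    if (step % save_every == 0 && isave < nsave) {
      frames.slice(isave) = x;
      series(isave, 0) = step;
      series(isave, 1) = compute_q(x);
      series(isave, 2) = cv;
      series(isave, 3) = rho;
      series(isave, 4) = bias_on ? rho_m : NA_REAL;
      series(isave, 5) = ebias;
      ++isave;
    }
    if (step == nsteps) break;

    // Euler-Maruyama update
    Rcpp::NumericVector xi = Rcpp::rnorm(3 * n);
    for (arma::uword i = 0; i < n; ++i) {
      for (int c = 0; c < 3; ++c) {
        x(i, c) += dt / gamma * F(i, c) + noise_scale * xi[3 * i + c];
      }
    }
    if (!x.is_finite() || arma::abs(x).max() > blow_threshold) {
      ok = false;
      break;
    }
  }

  const arma::cube out_frames = frames.slices(0, std::max(isave - 1, 0));
  const arma::mat out_series = series.rows(0, std::max(isave - 1, 0));
  return Rcpp::List::create(
    Rcpp::Named("frames") = out_frames,
    Rcpp::Named("series") = out_series,
    Rcpp::Named("ok") = ok,
    Rcpp::Named("rho_min") = rho_m);
}
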