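// FOCE-I engine: per-subject conditional-mode search and the linearized
// -2 log-likelihood contribution, kept in compiled code so that
// bootstrap-scale refitting stays cheap.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double CFLOOR = 1e-6;  // prediction floor inside the likelihood

// closed-form one-compartment oral model, t measured since this dose event
static double conc1(double ka, double v, double cl, double tlag,
                    double dose, double t) {
  double ke = cl / v;
  double tau = t - tlag;
  if (tau <= 0.0) return 0.0;
  if (std::abs(ka - ke) < 1e-8 * ke)
    return 1000.0 * dose / v * ke * tau * std::exp(-ke * tau);
  return 1000.0 * dose * ka / (v * (ka - ke)) *
         (std::exp(-ke * tau) - std::exp(-ka * tau));
}

struct Subj {
  vec t, y, dt, da;   // observation times/values, dose times/amounts
  double clm, vm;     // covariate multipliers on CL and V
};

static vec fpred(const Subj& s, const vec& th, const vec& eta) {
  double ka = th[0] * std::exp(eta[0]);
  double v  = th[1] * s.vm * std::exp(eta[1]);
  double cl = th[2] * s.clm * std::exp(eta[2]);
  vec f(s.t.n_elem, fill::zeros);
  for (uword j = 0; j < s.t.n_elem; ++j) {
    double c = 0.0;
    for (uword d = 0; d < s.dt.n_elem; ++d)
      c += conc1(ka, v, cl, th[3], s.da[d], s.t[j] - s.dt[d]);
    f[j] = c;
  }
  return f;
}

// -2 log joint density of (y, eta), additive constants dropped
static double gfun(const Subj& s, const vec& th, const vec& eta,
                   double sig2, const mat& Oinv, bool penalize) {
  vec f = clamp(fpred(s, th, eta), CFLOOR, datum::inf);
  vec r = s.y - f;
  double val = accu(square(r) / (sig2 * square(f)) + log(sig2 * square(f)));
  if (penalize) val += as_scalar(eta.t() * Oinv * eta);
  return val;
}

// d f / d eta by central differences
static mat fgrad(const Subj& s, const vec& th, const vec& eta) {
  const double h = 1e-4;
  mat G(s.t.n_elem, 3);
  for (int k = 0; k < 3; ++k) {
    vec ep = eta, em = eta;
    ep[k] += h; em[k] -= h;
    G.col(k) = (fpred(s, th, ep) - fpred(s, th, em)) / (2.0 * h);
  }
  return G;
}

// damped Gauss-Newton search for the conditional mode of eta
static int inner_mode(const Subj& s, const vec& th, double sig2,
                      const mat& Oinv, vec& eta, int max_iter) {
  double g = gfun(s, th, eta, sig2, Oinv, true);
  for (int iter = 0; iter < max_iter; ++iter) {
    mat F = fgrad(s, th, eta);
    vec f = clamp(fpred(s, th, eta), CFLOOR, datum::inf);
    vec r = s.y - f;
    vec w = 1.0 / (sig2 * square(f));
    vec grad = 2.0 * Oinv * eta;
    for (int k = 0; k < 3; ++k)
      grad[k] += accu(F.col(k) % (-2.0 * r % w - 2.0 * square(r) % w / f + 2.0 / f));
    if (norm(grad, "inf") < 1e-8) return 0;
    mat H = 2.0 * F.t() * diagmat(w) * F + 2.0 * Oinv;
    double lam = 1e-8;
    bool moved = false;
    for (int tries = 0; tries < 40; ++tries) {
      mat Hd = H;
      Hd.diag() += lam * (1.0 + abs(Hd.diag()));
      vec step;
      if (solve(step, Hd, -grad, solve_opts::likely_sympd + solve_opts::no_approx)) {
        vec cand = eta + step;
        double gc = gfun(s, th, cand, sig2, Oinv, true);
        if (std::isfinite(gc) && gc < g) {
          eta = cand; g = gc; moved = true; break;
        }
      }
      lam *= 10.0;
    }
    if (!moved) return (norm(grad, "inf") < 1e-5) ? 0 : 1;
  }
  return 0;  // hit iteration cap with monotone decrease: accept current mode
}

// [[Rcpp::export]]
Rcpp::List foce_ofv_cpp(Rcpp::List subjects, arma::vec theta, arma::mat omega,
                        double sigma, arma::mat eta_init, bool diagnostics,
                        int max_inner = 100) {
  const int n = subjects.size();
  const double sig2 = sigma * sigma;
  bool zero_omega = (norm(omega, "fro") < 1e-14);
  mat Oinv;
  if (!zero_omega) {
    mat om = omega;
    if (!inv_sympd(Oinv, om)) {
      om.diag() += 1e-10 * (1.0 + om.diag());
      if (!inv_sympd(Oinv, om))
        Rcpp::stop("omega is not invertible (not positive definite)");
    }
  }
  double ofv = 0.0;
  vec ofv_i(n, fill::zeros);
  mat eta_out(n, 3, fill::zeros);
  int n_fail = 0;
  std::vector<double> pred_all, ipred_all, cwres_all, iwres_all;

  for (int i = 0; i < n; ++i) {
    Rcpp::List si = subjects[i];
    Subj s;
    s.t   = Rcpp::as<vec>(si["t"]);
    s.y   = Rcpp::as<vec>(si["y"]);
    s.dt  = Rcpp::as<vec>(si["dose_t"]);
    s.da  = Rcpp::as<vec>(si["dose_a"]);
    s.clm = Rcpp::as<double>(si["clm"]);
    s.vm  = Rcpp::as<double>(si["vm"]);

    vec eta = zero_omega ? vec(3, fill::zeros) : eta_init.row(i).t();
    if (!zero_omega) {
      int rc = inner_mode(s, theta, sig2, Oinv, eta, max_inner);
      if (rc != 0) { n_fail++; ofv_i[i] = datum::inf; ofv = datum::inf; continue; }
    }
    vec f = clamp(fpred(s, theta, eta), CFLOOR, datum::inf);
    vec R = sig2 * square(f);
    mat G = fgrad(s, theta, eta);
    mat C = zero_omega ? mat(diagmat(R)) : mat(G * omega * G.t() + diagmat(R));
    vec r = s.y - f + G * eta;
    mat Lc;
    if (!chol(Lc, C, "lower")) {
      C.diag() += 1e-8 * mean(R);
      if (!chol(Lc, C, "lower")) {
        n_fail++; ofv_i[i] = datum::inf; ofv = datum::inf; continue;
      }
    }
    vec z = solve(trimatl(Lc), r);
    double li = 2.0 * accu(log(Lc.diag())) + dot(z, z);
    ofv_i[i] = li;
    if (std::isfinite(ofv)) ofv += li;
    eta_out.row(i) = eta.t();
    if (diagnostics) {
      vec f0 = fpred(s, theta, vec(3, fill::zeros));
      vec iw = (s.y - f) / (sigma * f);
      for (uword j = 0; j < s.t.n_elem; ++j) {
        pred_all.push_back(f0[j]);
        ipred_all.push_back(f[j]);
        cwres_all.push_back(z[j]);
        iwres_all.push_back(iw[j]);
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("ofv") = ofv,
    Rcpp::Named("ofv_i") = ofv_i,
    Rcpp::Named("eta") = eta_out,
    Rcpp::Named("n_fail") = n_fail);
  if (diagnostics) {
    out["pred"] = pred_all;
    out["ipred"] = ipred_all;
    out["cwres"] = cwres_all;
    out["iwres"] = iwres_all;
  }
  return out;
}
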