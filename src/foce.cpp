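// FOCE-I engine for the one-compartment IV-infusion model.
//
// Per subject: the conditional random-effect mode (eta-hat) is found by a
// damped Newton search on the penalized inner objective
//   h(eta) = sum_j [ (y_j - f_j(eta))^2 / g_j(eta) + log g_j(eta) ]
//            + eta' Omega^-1 eta
// with g evaluated at eta (the "interaction"), then the subject's -2LL
// contribution is the linearized marginal approximation
//   log|V| + r' V^-1 r,  V = G Omega G' + diag(g(eta-hat)),
//   r = y - f(eta-hat) + G eta-hat,  G = df/deta at eta-hat.
// The n*log(2*pi) constant is omitted, matching the usual OFV convention.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct SubjData {
  vec y, tobs;          // observations
  vec t0, amt, dur;     // infusion doses
  double clt, vt;       // typical CL and V (covariate factors applied)
  double om2cl, om2v;   // BSV variances
  double s2a, s2p;      // additive variance, proportional variance
  bool e1, e2;          // eta components estimated?
};

// one-compartment infusion superposition; expm1 keeps small-k accuracy
void conc_one(const vec& tobs, double cl, double v,
              const vec& t0, const vec& amt, const vec& dur, vec& out) {
  const double k = cl / v;
  out.zeros();
  for (uword d = 0; d < t0.n_elem; ++d) {
    const double R = amt[d] / dur[d];
    for (uword i = 0; i < tobs.n_elem; ++i) {
      const double te = tobs[i] - t0[d];
      if (te <= 0.0) continue;
      if (te <= dur[d])
        out[i] += (R / cl) * (-std::expm1(-k * te));
      else
        out[i] += (R / cl) * (-std::expm1(-k * dur[d])) *
                  std::exp(-k * (te - dur[d]));
    }
  }
}

vec fpred(const SubjData& S, const vec& eta) {
  const double cl = S.clt * std::exp(eta[0]);
  const double v  = S.vt * std::exp(eta[1]);
  vec f(S.y.n_elem);
  conc_one(S.tobs, cl, v, S.t0, S.amt, S.dur, f);
  return f;
}

// residual variance with interaction; prediction floored at 0.01 mg/l
// inside the variance so proportional error never degenerates
vec gvar(const SubjData& S, const vec& f) {
  vec fp = clamp(f, 0.01, datum::inf);
  return S.s2a + S.s2p * square(fp);
}

double hobj(const SubjData& S, const vec& eta, vec& f) {
  f = fpred(S, eta);
  const vec g = gvar(S, f);
  double h = accu(square(S.y - f) / g + log(g));
  if (S.e1) h += eta[0] * eta[0] / S.om2cl;
  if (S.e2) h += eta[1] * eta[1] / S.om2v;
  return h;
}

mat dfdeta(const SubjData& S, const vec& eta) {
  const double hs = 1e-4;
  mat G(S.y.n_elem, 2, fill::zeros);
  for (int j = 0; j < 2; ++j) {
    if ((j == 0 && !S.e1) || (j == 1 && !S.e2)) continue;
    vec ep = eta, em = eta;
    ep[j] += hs;
    em[j] -= hs;
    G.col(j) = (fpred(S, ep) - fpred(S, em)) / (2.0 * hs);
  }
  return G;
}

vec inner_eta(const SubjData& S, bool& ok) {
  vec eta(2, fill::zeros);
  ok = true;
  if (!S.e1 && !S.e2) return eta;
  vec f;
  double h = hobj(S, eta, f);
  ok = false;
  for (int it = 0; it < 100; ++it) {
    const mat G = dfdeta(S, eta);
    const vec g = gvar(S, f);
    const vec res = S.y - f;
    vec grad(2, fill::zeros);
    mat H(2, 2, fill::zeros);
    for (int j = 0; j < 2; ++j) {
      const bool est = (j == 0) ? S.e1 : S.e2;
      if (!est) continue;
      vec dg = 2.0 * S.s2p * clamp(f, 0.01, datum::inf) % G.col(j);
      for (uword i = 0; i < f.n_elem; ++i)
        if (f[i] < 0.01) dg[i] = 0.0;  // flat below the floor
      grad[j] = accu(-2.0 * res % G.col(j) / g -
                     square(res) / square(g) % dg + dg / g);
      grad[j] += 2.0 * eta[j] / ((j == 0) ? S.om2cl : S.om2v);
    }
    for (int j = 0; j < 2; ++j)
      for (int l = 0; l < 2; ++l) {
        const bool ej = (j == 0) ? S.e1 : S.e2;
        const bool el = (l == 0) ? S.e1 : S.e2;
        if (ej && el) H(j, l) = 2.0 * accu(G.col(j) % G.col(l) / g);
      }
    if (S.e1) H(0, 0) += 2.0 / S.om2cl; else H(0, 0) = 1.0;
    if (S.e2) H(1, 1) += 2.0 / S.om2v; else H(1, 1) = 1.0;

    const double gmax = std::max(std::abs(grad[0]), std::abs(grad[1]));
    if (gmax < 1e-6 * (1.0 + std::abs(h))) { ok = true; break; }

    vec step;
    if (!solve(step, H, -grad, solve_opts::no_approx + solve_opts::likely_sympd))
      step = -grad;
    // Armijo backtracking (Gauss-Newton direction is descent for this h)
    double s = 1.0;
    const double slope = dot(grad, step);
    bool improved = false;
    const double h_prev = h;
    for (int ls = 0; ls < 40; ++ls) {
      vec etan = eta + s * step;
      vec fnew;
      const double hnew = hobj(S, etan, fnew);
      if (std::isfinite(hnew) && hnew <= h + 1e-4 * s * slope) {
        eta = etan; f = fnew; h = hnew; improved = true; break;
      }
      s *= 0.5;
    }
    if (!improved) { ok = true; break; }  // stationary to line-search precision
    if (std::abs(h_prev - h) < 1e-9 * (1.0 + std::abs(h))) { ok = true; break; }
  }
  return eta;
}

}  // namespace

// [[Rcpp::export]]
List foce_engine_cpp(IntegerVector obs_start, IntegerVector obs_len,
                     NumericVector y_all, NumericVector t_all,
                     IntegerVector dose_start, IntegerVector dose_len,
                     NumericVector d_t0, NumericVector d_amt,
                     NumericVector d_dur,
                     NumericVector clt, NumericVector vt,
                     double om2_cl, double om2_v,
                     double sig2_add, double sig2_prop,
                     bool detail) {
  const int ns = obs_start.size();
  const int ntot = y_all.size();
  double ofv = 0.0;
  bool all_ok = true;

  NumericMatrix eta_out(detail ? ns : 0, 2);
  NumericVector pred_out(detail ? ntot : 0), ipred_out(detail ? ntot : 0),
      cwres_out(detail ? ntot : 0), sofv_out(detail ? ns : 0);

  for (int i = 0; i < ns; ++i) {
    SubjData S;
    const int o0 = obs_start[i], on = obs_len[i];
    const int q0 = dose_start[i], qn = dose_len[i];
    S.y = vec(&y_all[o0], on);
    S.tobs = vec(&t_all[o0], on);
    S.t0 = vec(&d_t0[q0], qn);
    S.amt = vec(&d_amt[q0], qn);
    S.dur = vec(&d_dur[q0], qn);
    S.clt = clt[i];
    S.vt = vt[i];
    S.om2cl = om2_cl;
    S.om2v = om2_v;
    S.s2a = sig2_add;
    S.s2p = sig2_prop;
    S.e1 = om2_cl > 0.0;
    S.e2 = om2_v > 0.0;

    bool ok = true;
    const vec eta = inner_eta(S, ok);
    all_ok = all_ok && ok;

    const vec f = fpred(S, eta);
    const mat G = dfdeta(S, eta);
    const vec g = gvar(S, f);

    mat V = diagmat(g);
    if (S.e1) V += om2_cl * (G.col(0) * G.col(0).t());
    if (S.e2) V += om2_v * (G.col(1) * G.col(1).t());
    const vec r = S.y - f + G * eta;

    mat L;
    if (!chol(L, V, "lower")) {
      V.diag() += 1e-8 * (1.0 + V.diag().max());
      if (!chol(L, V, "lower"))
        stop("FOCE covariance matrix not positive definite for subject %d",
             i + 1);
    }
    const double logdet = 2.0 * accu(log(L.diag()));
    const vec u = solve(trimatl(L), r);
    const double ofv_i = logdet + dot(u, u);
    ofv += ofv_i;

    if (detail) {
      eta_out(i, 0) = eta[0];
      eta_out(i, 1) = eta[1];
      sofv_out[i] = ofv_i;
      vec f0(on);
      conc_one(S.tobs, S.clt, S.vt, S.t0, S.amt, S.dur, f0);
      for (int j = 0; j < on; ++j) {
        pred_out[o0 + j] = f0[j];
        ipred_out[o0 + j] = f[j];
        cwres_out[o0 + j] = u[j];
      }
    }
  }

  if (!detail) return List::create(_["ofv"] = ofv, _["inner_ok"] = all_ok);
  return List::create(_["ofv"] = ofv, _["inner_ok"] = all_ok,
                      _["eta"] = eta_out, _["subject_ofv"] = sofv_out,
                      _["pred"] = pred_out, _["ipred"] = ipred_out,
                      _["cwres"] = cwres_out);
}
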