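// Conditional-estimation core: per-subject penalized Gauss-Newton mode
// search (Levenberg-Marquardt damped, multistart) and the Laplace /
// FOCE marginal-likelihood approximation, for the one-compartment
// IV-infusion model with log-normal random effects on CL and V and an
// additive residual on the log scale.
//
// Data layout (built by the R flattening step): observations are
// grouped by subject, and each observation carries a contiguous run of
// (dose) pairs; n_i gives observations per subject, pair_count pairs
// per observation.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct ObsWork {
  // per-observation model quantities at the current eta
  std::vector<double> m, r, J1, J2, S11, S12, S22;
  void resize(int n) {
    m.resize(n); r.resize(n); J1.resize(n); J2.resize(n);
    S11.resize(n); S12.resize(n); S22.resize(n);
  }
};

// Evaluate log-concentration and derivatives for observations
// [o0, o0+nobs) of one subject at individual (cl, v). Returns false if
// any predicted concentration is non-positive.
bool profile_subject(int o0, int nobs, int p0,
                     const double* obs_time, const double* ldv,
                     const int* pair_count,
                     const double* p_t0, const double* p_dur,
                     const double* p_rate,
                     double cl, double v, bool want_hess,
                     ObsWork& W, int offset) {
  double k = cl / v;
  int pp = p0;
  for (int j = 0; j < nobs; ++j) {
    double t = obs_time[o0 + j];
    double C = 0.0, Q = 0.0, U = 0.0;
    int np = pair_count[o0 + j];
    for (int q = 0; q < np; ++q, ++pp) {
      double dt = t - p_t0[pp];
      if (dt <= 0.0) continue;
      double dur = p_dur[pp];
      double te = dt < dur ? dt : dur;
      double tail = dt > dur ? dt - dur : 0.0;
      double E1 = std::exp(-k * te);
      double E2 = std::exp(-k * tail);
      double B = p_rate[pp] / cl;
      double phi0 = (1.0 - E1) * E2;
      double phi1 = E2 * (te * E1 - tail * (1.0 - E1));
      C += B * phi0;
      Q += B * k * phi1;
      if (want_hess) {
        double phi2 = -E2 * (te * E1 * (te + 2.0 * tail) -
                             tail * tail * (1.0 - E1));
        U += B * (k * k * phi2 + k * phi1);
      }
    }
    if (!(C > 0.0) || !std::isfinite(C)) return false;
    int jj = offset + j;
    W.m[jj] = std::log(C);
    W.r[jj] = ldv[o0 + j] - W.m[jj];
    double J1 = Q / C - 1.0, J2 = -Q / C;
    W.J1[jj] = J1;
    W.J2[jj] = J2;
    if (want_hess) {
      W.S11[jj] = (C - 2.0 * Q + U) / C - J1 * J1;
      W.S12[jj] = (Q - U) / C - J1 * J2;
      W.S22[jj] = U / C - J2 * J2;
    }
  }
  return true;
}

inline double pen_obj(const ObsWork& W, int nobs, double s2,
                      double e1, double e2, double io1, double io2) {
  double rss = 0.0;
  for (int j = 0; j < nobs; ++j) rss += W.r[j] * W.r[j];
  return rss / s2 + e1 * e1 * io1 + e2 * e2 * io2;
}

}  // namespace

// [[Rcpp::export(name = ".foce_core")]]
List foce_core(IntegerVector n_i, NumericVector obs_time,
               NumericVector ldv, IntegerVector pair_count,
               NumericVector p_t0, NumericVector p_dur,
               NumericVector p_rate,
               NumericVector base_cl, NumericVector base_v,
               double omega2_cl, double omega2_v, double sigma2,
               NumericMatrix starts, bool laplace,
               double tol, int max_iter) {
  const int ns = n_i.size();
  const int n_obs = obs_time.size();
  const int K = starts.nrow();
  const double o1 = std::max(omega2_cl, 1e-12);
  const double o2 = std::max(omega2_v, 1e-12);
  const double s2 = sigma2;
  const double io1 = 1.0 / o1, io2 = 1.0 / o2;

  NumericVector eta1(ns), eta2(ns), ofv_i(ns);
  NumericVector m_out(n_obs), r_out(n_obs), J1_out(n_obs),
      J2_out(n_obs);
  int bad_obs = -1;

  ObsWork W, Wt, Wbest;
  int o0 = 0, p0 = 0;
  for (int i = 0; i < ns; ++i) {
    const int nobs = n_i[i];
    int np_subject = 0;
    for (int j = 0; j < nobs; ++j) np_subject += pair_count[o0 + j];
    double best_f = R_PosInf, best_e1 = 0.0, best_e2 = 0.0;
    W.resize(nobs); Wt.resize(nobs); Wbest.resize(nobs);

    if (nobs == 0) {
      ofv_i[i] = 0.0;
      // prior mode; nothing else to do
      o0 += nobs; p0 += np_subject;
      continue;
    }

    for (int s = 0; s < K; ++s) {
      double e1 = starts(s, 0), e2 = starts(s, 1);
      if (!profile_subject(o0, nobs, p0, obs_time.begin(), ldv.begin(),
                           pair_count.begin(), p_t0.begin(),
                           p_dur.begin(), p_rate.begin(),
                           base_cl[i] * std::exp(e1),
                           base_v[i] * std::exp(e2), false, W, 0)) {
        if (s == 0) { bad_obs = o0; break; }
        continue;
      }
      double f = pen_obj(W, nobs, s2, e1, e2, io1, io2);
      double lam = 0.0;
      for (int it = 0; it < max_iter; ++it) {
        double A11 = io1, A12 = 0.0, A22 = io2, g1 = -e1 * io1,
               g2 = -e2 * io2;
        for (int j = 0; j < nobs; ++j) {
          A11 += W.J1[j] * W.J1[j] / s2;
          A12 += W.J1[j] * W.J2[j] / s2;
          A22 += W.J2[j] * W.J2[j] / s2;
          g1 += W.J1[j] * W.r[j] / s2;
          g2 += W.J2[j] * W.r[j] / s2;
        }
        // undamped step decides convergence
        double det0 = A11 * A22 - A12 * A12;
        double d1_0 = (A22 * g1 - A12 * g2) / det0;
        double d2_0 = (A11 * g2 - A12 * g1) / det0;
        if (std::fabs(d1_0) < tol && std::fabs(d2_0) < tol) break;
        double b11 = A11 * (1.0 + lam), b22 = A22 * (1.0 + lam);
        double det = b11 * b22 - A12 * A12;
        double d1 = (b22 * g1 - A12 * g2) / det;
        double d2 = (b11 * g2 - A12 * g1) / det;
        double t1 = e1 + d1, t2 = e2 + d2;
        if (t1 > 8.0) t1 = 8.0; else if (t1 < -8.0) t1 = -8.0;
        if (t2 > 8.0) t2 = 8.0; else if (t2 < -8.0) t2 = -8.0;
        bool fin = profile_subject(o0, nobs, p0, obs_time.begin(),
                                   ldv.begin(), pair_count.begin(),
                                   p_t0.begin(), p_dur.begin(),
                                   p_rate.begin(),
                                   base_cl[i] * std::exp(t1),
                                   base_v[i] * std::exp(t2), false,
                                   Wt, 0);
        double ft = fin ? pen_obj(Wt, nobs, s2, t1, t2, io1, io2)
                        : R_PosInf;
        if (fin && ft <= f + 1e-12) {
          e1 = t1; e2 = t2; f = ft;
          std::swap(W.m, Wt.m); std::swap(W.r, Wt.r);
          std::swap(W.J1, Wt.J1); std::swap(W.J2, Wt.J2);
          lam /= 3.0;
          if (lam < 1e-8) lam = 0.0;
        } else {
          lam = std::max(lam * 5.0, 1.0);
          if (lam > 1e10) break;
        }
      }
      if (f < best_f - 1e-12) {
        best_f = f; best_e1 = e1; best_e2 = e2;
        std::swap(Wbest.m, W.m); std::swap(Wbest.r, W.r);
        std::swap(Wbest.J1, W.J1); std::swap(Wbest.J2, W.J2);
      }
    }
    if (bad_obs >= 0) break;

    eta1[i] = best_e1;
    eta2[i] = best_e2;
    // final profile with curvature at the mode
    profile_subject(o0, nobs, p0, obs_time.begin(), ldv.begin(),
                    pair_count.begin(), p_t0.begin(), p_dur.begin(),
                    p_rate.begin(), base_cl[i] * std::exp(best_e1),
                    base_v[i] * std::exp(best_e2), true, W, 0);
    double A11 = 0.0, A12 = 0.0, A22 = 0.0, rr = 0.0;
    double P11 = 0.0, P12 = 0.0, P22 = 0.0;
    for (int j = 0; j < nobs; ++j) {
      A11 += W.J1[j] * W.J1[j];
      A12 += W.J1[j] * W.J2[j];
      A22 += W.J2[j] * W.J2[j];
      rr += W.r[j] * W.r[j];
      P11 -= W.r[j] * W.S11[j];
      P12 -= W.r[j] * W.S12[j];
      P22 -= W.r[j] * W.S22[j];
      m_out[o0 + j] = W.m[j];
      r_out[o0 + j] = W.r[j];
      J1_out[o0 + j] = W.J1[j];
      J2_out[o0 + j] = W.J2[j];
    }
    double ld_gn = std::log((1.0 + o1 * A11 / s2) *
                            (1.0 + o2 * A22 / s2) -
                            (o1 * A12 / s2) * (o2 * A12 / s2));
    double ld, quad;
    if (laplace) {
      P11 += A11; P12 += A12; P22 += A22;
      double det_lap = (1.0 + o1 * P11 / s2) * (1.0 + o2 * P22 / s2) -
          (o1 * P12 / s2) * (o2 * P12 / s2);
      ld = det_lap > 1e-10 ? std::log(det_lap) : ld_gn;
      quad = rr / s2 + best_e1 * best_e1 * io1 +
          best_e2 * best_e2 * io2;
    } else {
      // linearized (classical FOCE) form via the 2x2 Woodbury
      // complement of sigma2 I + G Omega G'
      double ee = 0.0, Ge1 = 0.0, Ge2 = 0.0;
      for (int j = 0; j < nobs; ++j) {
        double e = W.r[j] + W.J1[j] * best_e1 + W.J2[j] * best_e2;
        ee += e * e;
        Ge1 += W.J1[j] * e;
        Ge2 += W.J2[j] * e;
      }
      double d11 = io1 + A11 / s2, d12 = A12 / s2,
             d22 = io2 + A22 / s2;
      double detD = d11 * d22 - d12 * d12;
      ld = ld_gn;
      quad = ee / s2 -
          (d22 * Ge1 * Ge1 - 2.0 * d12 * Ge1 * Ge2 +
           d11 * Ge2 * Ge2) / detD / (s2 * s2);
    }
    ofv_i[i] = nobs * std::log(2.0 * M_PI * s2) + ld + quad;
    o0 += nobs;
    p0 += np_subject;
  }

  double ofv = 0.0;
  for (int i = 0; i < ns; ++i) ofv += ofv_i[i];
  return List::create(_["ofv"] = ofv, _["ofv_i"] = ofv_i,
                      _["eta1"] = eta1, _["eta2"] = eta2,
                      _["m"] = m_out, _["r"] = r_out,
                      _["J1"] = J1_out, _["J2"] = J2_out,
                      _["bad_obs"] = bad_obs + 1);
}
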